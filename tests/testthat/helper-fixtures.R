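# Shared fixtures: cached reference tables and the worked reference
# scenario (KILLER powder product, 10 ha, open-cockpit tractor, no PPE).

.fixture_env <- new.env()

demo_tables <- function() {
  if (is.null(.fixture_env$tables))
    .fixture_env$tables <- load_reference_tables(default_tables_dir())
  .fixture_env$tables
}

killer_yaml <- function(ppe_block = "") {
  paste0("
crop: {name: olive, height: high}
pest: olive fruit fly
area_ha: 10
product: {name: KILLER}
application:
  spray_volume_hl_per_ha: 10
  tank_volume_l: 1000
  pressure_bar: 3
  equipment: tractor_open
operator: {body_weight_kg: 60}
", ppe_block)
}

killer_scenario <- function(ppe_block = "") {
  parse_scenario(killer_yaml(ppe_block))
}

# set one PPE slot on an existing scenario
with_ppe <- function(scenario, phase, region, item) {
  scenario$ppe[[phase]][[region]] <- item
  scenario
}

# copy of the packaged tables directory with one cell edited via a callback
edited_tables_dir <- function(edit) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  build_demo_database(dir)
  edit(dir)
  dir
}
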