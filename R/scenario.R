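# Scenario: typed representation, parsing and validation of one planned
# pesticide treatment (one product, one workday).

DEFAULT_BODY_WEIGHT_KG <- 60  # EFSA operator-exposure convention

# Parse structured config text; YAML is the primary dialect, JSON the
# documented alternate (a JSON document is valid YAML, but jsonlite gives
# sharper errors for it, so detect it first).
parse_structured_text <- function(text) {
  trimmed <- trimws(text)
  if (startsWith(trimmed, "{") || startsWith(trimmed, "[")) {
    jsonlite::fromJSON(text, simplifyVector = TRUE)
  } else {
    yaml::yaml.load(text)
  }
}

scalar_or <- function(x, default) if (is.null(x)) default else x

require_key <- function(raw, path) {
  node <- raw
  for (key in path) {
    node <- node[[key]]
    if (is.null(node))
      stop(sprintf("scenario config is missing required key '%s'",
                   paste(path, collapse = ".")), call. = FALSE)
  }
  node
}

#' Parse a scenario configuration
#'
#' Accepts the documented YAML schema (JSON as alternate) with sections
#' `crop`, `product`, `application`, `ppe.{mixing_loading,application,
#' maintenance}` and `operator`. Missing optional keys are filled with
#' defaults and recorded in the parse log (attribute `"parse_log"`).
#'
#' Required keys: `area_ha` and `product.name`. Defaults: equipment
#' `tractor_open`; spray volume 10 hL/ha; tank 1000 L; pressure 3 bar; all
#' PPE `"none"`; body weight 60 kg; `skip_mixing_loading` false; crop height
#' from the packaged crop-name lookup, else `"low"`.
#'
#' @param config_text Scenario configuration as a single string, or a path
#'   to a file containing it.
#' @return A validated object of class `scenario`.
#' @seealso [validate_scenario()], [serialize_scenario()]
#' @export
parse_scenario <- function(config_text) {
  if (length(config_text) == 1 && !grepl("\n", config_text) &&
      file.exists(config_text))
    config_text <- paste(readLines(config_text, warn = FALSE), collapse = "\n")
  raw <- parse_structured_text(config_text)
  if (!is.list(raw))
    stop("scenario config must be a mapping of sections", call. = FALSE)
  log <- character(0)
  note <- function(msg) log <<- c(log, msg)

  area <- require_key(raw, "area_ha")
  if (!is.numeric(area) || !is.finite(area) || area <= 0)
    stop("scenario key 'area_ha' must be a positive number", call. = FALSE)

  product_name <- require_key(raw, c("product", "name"))
  if (!is.null(raw$products) || length(raw$product$name) > 1)
    stop("only one product per scenario is supported; tank mixes are rejected",
         call. = FALSE)

  crop_name <- scalar_or(raw$crop$name, "unspecified")
  crop_height <- raw$crop$height
  if (is.null(crop_height)) {
    crop_height <- crop_height_for(crop_name)
    if (is.na(crop_height)) {
      crop_height <- "low"
      note(sprintf("crop.height defaulted to 'low' (crop '%s' not in lookup)",
                   crop_name))
    } else {
      note(sprintf("crop.height '%s' resolved from crop-name lookup", crop_height))
    }
  }
  if (!crop_height %in% c("low", "high"))
    stop("crop.height must be 'low' or 'high'", call. = FALSE)

  app <- raw$application
  fill <- function(value, default, key) {
    if (is.null(value)) {
      note(sprintf("%s defaulted to %s", key, format(default)))
      default
    } else value
  }
  application <- list(
    spray_volume_hl_per_ha = fill(app$spray_volume_hl_per_ha, 10,
                                  "application.spray_volume_hl_per_ha"),
    tank_volume_l = fill(app$tank_volume_l, 1000, "application.tank_volume_l"),
    pressure_bar = fill(app$pressure_bar, 3, "application.pressure_bar"),
    equipment = fill(app$equipment, "tractor_open", "application.equipment"))
  if (application$spray_volume_hl_per_ha <= 0)
    stop("application.spray_volume_hl_per_ha must be > 0", call. = FALSE)
  if (application$tank_volume_l <= 0)
    stop("application.tank_volume_l must be > 0", call. = FALSE)
  if (application$pressure_bar < 0)
    stop("application.pressure_bar must be >= 0", call. = FALSE)

  ppe <- lapply(WORK_PHASES, function(phase) {
    sel <- raw$ppe[[phase]]
    items <- vapply(BODY_REGIONS, function(region) {
      item <- sel[[region]]
      if (is.null(item)) {
        note(sprintf("ppe.%s.%s defaulted to 'none'", phase, region))
        "none"
      } else as.character(item)
    }, character(1))
    as.list(items)
  })
  names(ppe) <- WORK_PHASES

  body_weight <- scalar_or(raw$operator$body_weight_kg, NA_real_)
  if (is.na(body_weight)) {
    body_weight <- DEFAULT_BODY_WEIGHT_KG
    note(sprintf("operator.body_weight_kg defaulted to %g", body_weight))
  }
  if (!is.finite(body_weight) || body_weight <= 0)
    stop("operator.body_weight_kg must be > 0", call. = FALSE)

  structure(list(crop = list(name = crop_name, height = crop_height),
                 pest = scalar_or(raw$pest, ""),
                 area_ha = area,
                 product_name = product_name,
                 application = application,
                 ppe = ppe,
                 body_weight_kg = body_weight,
                 skip_mixing_loading = isTRUE(raw$skip_mixing_loading)),
            class = "scenario", parse_log = log)
}

#' Serialize a scenario back to YAML
#'
#' Round-trips with [parse_scenario()]: parsing the serialized text yields a
#' scenario with identical fields.
#'
#' @param scenario A `scenario` object.
#' @return A single YAML string.
#' @export
serialize_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario"))
  yaml::as.yaml(precision = 17L, list(
    crop = scenario$crop,
    pest = scenario$pest,
    area_ha = scenario$area_ha,
    product = list(name = scenario$product_name),
    application = scenario$application,
    ppe = scenario$ppe,
    operator = list(body_weight_kg = scenario$body_weight_kg),
    skip_mixing_loading = scenario$skip_mixing_loading))
}

#' Crop height (low/high) for a crop name
#'
#' Uses the editable lookup shipped at `inst/extdata/crop_heights.csv`
#' (e.g. cereals are low crops; vineyard and olive are high crops, where the
#' spray is directed upwards). Unknown crops return `NA` and must state
#' their height explicitly.
#'
#' @param crop_name Free-text crop name (case-insensitive).
#' @return `"low"`, `"high"`, or `NA_character_`.
#' @export
crop_height_for <- function(crop_name) {
  path <- file.path(default_tables_dir(), "crop_heights.csv")
  lookup <- read_ref_csv(path)
  lookup$height[match(tolower(trimws(crop_name)), lookup$crop)][1]
}

finding <- function(severity, field, message) {
  data.frame(severity = severity, field = field, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a scenario against the reference tables
#'
#' Checks that every reference (product, equipment, PPE item) resolves and
#' every numeric invariant holds. Returns findings, not exceptions: a data
#' frame with columns `severity` (`error`, `warning`, `info`), `field` and
#' `message`; an empty frame means the scenario is fully valid.
#'
#' @param scenario A `scenario` object.
#' @param tables A `reference_tables` object.
#' @return A data frame of findings (zero rows when valid).
#' @export
validate_scenario <- function(scenario, tables) {
  stopifnot(inherits(scenario, "scenario"), inherits(tables, "reference_tables"))
  out <- finding(character(0), character(0), character(0))
  add <- function(...) out <<- rbind(out, finding(...))

  if (scenario$area_ha <= 0)
    add("error", "area_ha", "treated area must be positive")
  if (scenario$body_weight_kg <= 0)
    add("error", "operator.body_weight_kg", "body weight must be positive")

  product <- tryCatch(get_product(tables, scenario$product_name),
                      error = function(e) {
                        add("error", "product.name", conditionMessage(e))
                        NULL
                      })
  if (!scenario$application$equipment %in% EQUIPMENT_TYPES)
    add("error", "application.equipment",
        sprintf("unknown equipment '%s'", scenario$application$equipment))

  for (phase in WORK_PHASES) for (region in BODY_REGIONS) {
    item <- scenario$ppe[[phase]][[region]]
    if (identical(item, "none")) next
    if (!item %in% tables$protection$item) {
      add("error", sprintf("ppe.%s.%s", phase, region),
          sprintf("unknown PPE item '%s'", item))
    } else if (!region %in% trimws(strsplit(
        tables$protection$body_region_applicability[
          match(item, tables$protection$item)], ";", fixed = TRUE)[[1]])) {
      add("warning", sprintf("ppe.%s.%s", phase, region),
          sprintf("item '%s' is not designed for the %s region", item, region))
    }
  }

  if (!is.null(product)) {
    if (product$formulation == "soluble_bag" &&
        !identical(scenario$ppe$mixing_loading$hands, "none"))
      add("warning", "ppe.mixing_loading.hands",
          "M&L exposure is zero for soluble bags; gloves in this phase have no effect on the estimate")
    for (phase in c("mixing_loading", "maintenance")) {
      if (phase == "mixing_loading" &&
          (scenario$skip_mixing_loading || product$formulation == "soluble_bag"))
        next
      if (identical(scenario$ppe[[phase]]$hands, "none"))
        add("warning", sprintf("ppe.%s.hands", phase),
            sprintf("bare hands in the manual %s phase; hand contamination (and glove re-donning, which the model does not quantify) dominates exposure here",
                    gsub("_", " & ", phase)))
    }
  }
  if (scenario$skip_mixing_loading)
    add("info", "skip_mixing_loading",
        "M&L phase excluded from assessment (product loaded at a loading station)")
  out
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("Treatment scenario: %s on %s (%s crop), %g ha\n",
              x$product_name, x$crop$name, x$crop$height, x$area_ha))
  cat(sprintf("  application: %s, %g hL/ha, %g L tank, %g bar\n",
              x$application$equipment, x$application$spray_volume_hl_per_ha,
              x$application$tank_volume_l, x$application$pressure_bar))
  for (phase in WORK_PHASES) {
    items <- unlist(x$ppe[[phase]])
    worn <- items[items != "none"]
    cat(sprintf("  PPE %-14s: %s\n", phase,
                if (length(worn)) paste(sprintf("%s=%s", names(worn), worn),
                                        collapse = ", ") else "none"))
  }
  cat(sprintf("  operator: %g kg%s\n", x$body_weight_kg,
              if (x$skip_mixing_loading) "; M&L skipped" else ""))
  invisible(x)
}
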