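# pestrisk reference table 'formulation' v1
# Mixing-and-loading contact fraction per formulation and AI-concentration
# band (percent, half-open-left: [0,30) [30,60) [60,80) [80,100]).
# Fractions are dimensionless (table prints percent; 0.045% -> 0.00045).
# Note: the endorsed table ranks liquid concentrate above powder even
# though narrative accounts rank powders as the most contaminating form;
# the printed table values are authoritative here.
# Soluble granules share the liquid_concentrate row (alias, not a row).
formulation,band_lo,band_hi,fraction
soluble_bag,0,30,0
soluble_bag,30,60,0
soluble_bag,60,80,0
soluble_bag,80,100,0
liquid_concentrate,0,30,0.0003
liquid_concentrate,30,60,0.00045
liquid_concentrate,60,80,0.0007
liquid_concentrate,80,100,0.0009
powder,0,30,0.00003
powder,30,60,0.00005
powder,60,80,0.00007
powder,80,100,0.00009
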