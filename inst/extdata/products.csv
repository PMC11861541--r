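# pestrisk reference table 'products' v1
# Demonstration active-ingredient database (16 entries). Row 1 is the
# worked exercise product; all DEMO- entries are synthetic and must not
# be mistaken for real authorization records.
product_name,ai_name,formulation,concentration_pct,gap_g_per_ha,aoel_mg_per_kg,dermal_absorption_pct
KILLER,ACTIVOL,powder,50,100,0.05,5
DEMO-FUNGON,DEMO-AZOLINE,powder,80,500,0.02,10
DEMO-DUSTIT,DEMO-CARBAXIM,powder,25,300,0.001,2
DEMO-POWDRIX,DEMO-THIOPRAM,powder,65,800,0.2,8
DEMO-LIQUIFOS,DEMO-FOSETHION,liquid_concentrate,40,1500,0.005,20
DEMO-HERBAX,DEMO-GLUFOTRIN,liquid_concentrate,36,2000,0.1,10
DEMO-OLEOGARD,DEMO-OLEANIL,liquid_concentrate,15,1200,0.05,25
DEMO-VINCLEAR,DEMO-PYRALOX,liquid_concentrate,70,600,0.5,5
DEMO-MAXITOX,DEMO-DIMETHRIN,liquid_concentrate,90,250,0.01,30
DEMO-GRANUFLOW,DEMO-CUPRONEX,soluble_granule,70,3000,1,1
DEMO-SOLUGRAN,DEMO-METIRAM,soluble_granule,55,1800,0.08,4
DEMO-PELLETIX,DEMO-ZOXAFEN,soluble_granule,30,900,0.3,6
DEMO-SAFEBAG,DEMO-ACARIDON,soluble_bag,85,400,0.01,15
DEMO-BAGPRO,DEMO-FLURAZEN,soluble_bag,50,700,0.04,12
DEMO-ENVELOPE,DEMO-TEBUMOL,soluble_bag,95,200,0.002,18
DEMO-MIXSAFE,DEMO-PROPIZOL,soluble_bag,20,1000,0.6,9
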