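# pestrisk reference table 'protection' v1
# Fraction of deposited product retained by the item (kept off the skin).
# source=reference: endorsed clothing table; source=default: package
# defaults for item classes the endorsed table does not price, chosen
# consistently with its generic-vs-technical span and flagged in audits.
item,body_region_applicability,fraction,source
underwear,body,0.50,reference
generic_clothes,body,0.70,reference
cotton_coverall,body,0.90,reference
nonwoven_coverall,body,0.90,reference
hazmat_coverall,body,0.99,reference
generic_gloves,hands,0.90,default
specific_gloves,hands,0.99,default
headdress,head,0.90,default
mask,face,0.90,default
shoes,feet,0.70,default
boots,feet,0.99,default
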