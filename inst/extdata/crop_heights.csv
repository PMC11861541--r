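# pestrisk crop-height lookup v1 (editable)
# low: spray directed downwards (herbicides on field crops);
# high: spray directed upwards (bush and tree crops).
crop,height
cereals,low
wheat,low
barley,low
maize,low
rice,low
potato,low
sugar beet,low
soybean,low
tomato,low
vineyard,high
grape,high
olive,high
apple,high
pear,high
peach,high
citrus,high
orchard,high
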