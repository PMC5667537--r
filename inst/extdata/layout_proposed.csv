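habitat,area_m2
hard-standing,9525.16
amenity grass/turf,1573.91
introduced shrubs,1346.69
neutral grassland,2133.45
broadleaved woodland,3477.67
short/perennial vegetation,0
chalk grassland,526
ponds,459.37
marginal vegetation,99.15
species-rich hedgerow,607.5
species-poor hedgerow,0
acid grassland,82
fen,133.86
green roof,0
ferns and cycad planting,729.82
agricultural plants,583.97
cretaceous angiosperm shrubs,244.97
paleogene asteraceae,176.57
neogene grass,156.27
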