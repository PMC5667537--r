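habitat,area_m2
hard-standing,10415
amenity grass/turf,3303.63
introduced shrubs,2218.62
neutral grassland,2103.15
broadleaved woodland,1978.36
short/perennial vegetation,423.65
chalk grassland,344.58
ponds,341.28
marginal vegetation,163.6
species-rich hedgerow,121.87
species-poor hedgerow,109
acid grassland,100
fen,64.6
green roof,9.98
ferns and cycad planting,0
agricultural plants,0
cretaceous angiosperm shrubs,0
paleogene asteraceae,0
neogene grass,0
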