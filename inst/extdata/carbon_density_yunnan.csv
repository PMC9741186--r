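class,above,below,soil,dead
cropland,27.89,62,47.52,1
forest_land,48.18,131.7,49.24,29
grassland,38.24,95.6,50.45,1
water_area,27.55,0,43.53,0
construction_land,26.43,0,47.48,0
unused_land,30.23,0,40.75,3
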