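class,cropland,forest_land,grassland,water_area,construction_land,unused_land
cropland,31070.15,18651.90,14217.83,594.51,2436.57,33.99
forest_land,23641.68,157653.31,36907.57,449.05,342.58,266.83
grassland,11122.83,22203.35,50912.78,438.06,332.14,731.90
water_area,638.83,864.14,850.93,1339.49,96.29,1.48
construction_land,1695.01,633.32,871.75,124.14,1444.72,0.95
unused_land,68.80,268.41,345.90,50.11,38.44,752.71
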