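class,cropland,forest_land,grassland,water_area,construction_land,unused_land
cropland,31707.80,22223.81,12076.72,690.02,2551.25,49.10
forest_land,21188.40,167415.10,27970.77,937.41,764.68,296.13
grassland,12648.76,28672.68,44340.97,782.59,801.74,307.26
water_area,556.60,427.43,393.49,1315.71,88.91,13.22
construction_land,839.59,187.75,153.05,40.58,560.42,5.02
unused_land,63.81,335.04,806.10,24.85,2.89,853.64
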