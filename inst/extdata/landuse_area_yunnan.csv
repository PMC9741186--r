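class,1990,2000,2015,2018,2020
cropland,69371,69001,67688,67247,67105
forest_land,218881,218421,220225,219869,219823
grassland,87732,88292,86586,86051,85995
water_area,2805,2831,3239,3843,3838
construction_land,1788,2031,3777,4513,4775
unused_land,2105,2105,1561,1553,1540
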