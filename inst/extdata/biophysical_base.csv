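base_class,albedo,kc,green_area
water,0.08,1.00,TRUE
forest,0.12,1.00,TRUE
garden,0.16,0.85,TRUE
building,0.25,0.00,FALSE
road_path,0.14,0.00,FALSE
sidewalk,0.18,0.00,FALSE
traffic_island,0.16,0.40,FALSE
other_impervious,0.17,0.00,FALSE
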