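"condition_kind","condition_value","time_min","residual_pct"
"temperature",60,0,103.839016775167
"temperature",60,5,69.7490255342329
"temperature",60,10,46.8842398614899
"temperature",60,15,35.4661292429483
"temperature",60,20,26.806812523818
"temperature",60,25,20.6312004819188
"temperature",60,30,11.4881212795305
"temperature",60,35,7.82814189966789
"temperature",60,40,5.9776141453237
"temperature",60,45,5.77536296333377
"temperature",60,50,5.46799705628373
"temperature",60,55,4.11971246515769
"temperature",60,60,0.988905720132954
"temperature",70,0,101.897665076482
"temperature",70,10,73.7987016355731
"temperature",70,20,51.961206545495
"temperature",70,30,31.9650630438755
"temperature",70,40,29.3475826206732
"temperature",70,50,17.5054013759678
"temperature",70,60,16.9139752427762
"temperature",70,70,5.74894453433598
"temperature",70,80,4.71847504394195
"temperature",70,90,7.60528611391706
"temperature",70,100,1.95878142667112
"temperature",70,110,2.47440138537989
"temperature",70,120,3.18748342834645
"pH",6,0,100.358380347172
"pH",6,30,85.7600415839383
"pH",6,60,78.0066454417416
"pH",6,90,67.8305999089529
"pH",6,120,55.5160916016909
"pH",6,150,47.3277636095328
"pH",6,180,44.0640961340911
"pH",6,210,37.161285814019
"pH",6,240,32.3502591638778
"pH",6,270,26.7131822473987
"pH",6,300,28.9798742908073
"pH",6,330,22.6423062205488
"pH",6,360,19.4681662065512
"pH",6,390,18.3532361625115
"pH",6,420,16.6227463794071
"pH",6,450,17.8143949029294
"pH",6,480,8.91512423948093
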