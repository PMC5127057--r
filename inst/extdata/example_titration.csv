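"protease_id","ratio","fractional_activity","enzyme_uM"
"HNE",0,1.01919508387583,0.2
"HNE",0.5,0.711100827986981,0.2
"HNE",1,0.416239381125631,0.2
"HNE",1.5,0.148281223645377,0.2
"HNE",2,0.00903406261909016,0.2
"HNE",2.5,0.0147676547612758,0.2
"HNE",3,0,0.2
"HNE",3.5,0,0.2
"HNE",4,0,0.2
"HNE",4.5,0.00677972790458922,0.2
"HNE",5,0.0117149852814186,0.2
"HNE",5.5,0.00955001886974866,0.2
"HNE",6,0,0.2
"HNE",6.5,0,0.2
"HNE",7,0,0.2
"HNE",7.5,0.00139138809327379,0.2
"HNE",8,0.00702652685875945,0.2
"HNE",8.5,0,0.2
"HNE",9,0,0.2
"HNE",9.5,0.0145997495164358,0.2
"HNE",10,0,0.2
"PR3",0,1.00948832538241,0.3
"PR3",0.5,0.555011379271156,0.3
"PR3",1,0.0923256778848089,0.3
"PR3",1.5,0,0.3
"PR3",2,0.0132077017515656,0.3
"PR3",2.5,0,0.3
"PR3",3,0.0155642816092675,0.3
"PR3",3.5,0,0.3
"PR3",4,0,0.3
"PR3",4.5,0.0123909506943466,0.3
"PR3",5,0,0.3
"PR3",5.5,0,0.3
"PR3",6,0.00641387296825978,0.3
"PR3",6.5,0,0.3
"PR3",7,0.00914187764481792,0.3
"PR3",7.5,0,0.3
"PR3",8,0.00107470123519121,0.3
"PR3",8.5,0,0.3
"PR3",9,0,0.3
"PR3",9.5,0.00468782227495526,0.3
"PR3",10,0,0.3
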