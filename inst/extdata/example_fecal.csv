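"group_label","replicate_id","activity"
"PBS","PBS_1",1.55629865332459
"PBS","PBS_2",0.861826171256514
"PBS","PBS_3",0.661070626848899
"PBS","PBS_4",0.983465329538074
"PBS","PBS_5",1.21182197381572
"PBS","PBS_6",1.39556295312567
"PBS","PBS_7",0.856513634283869
"PBS","PBS_8",0.856638686735113
"DSS","DSS_1",1.58064316156508
"DSS","DSS_2",2.01131751856789
"DSS","DSS_3",2.49581740787863
"DSS","DSS_4",1.88275884352786
"DSS","DSS_5",2.621228277851
"DSS","DSS_6",1.25048843636226
"DSS","DSS_7",2.41985439911903
"DSS","DSS_8",2.36368392000499
"DSS+serpin1","DSS+serpin1_1",1.82126768091702
"DSS+serpin1","DSS+serpin1_2",1.99786519398009
"DSS+serpin1","DSS+serpin1_3",1.63532004903838
"DSS+serpin1","DSS+serpin1_4",1.75818330930807
"DSS+serpin1","DSS+serpin1_5",1.33250245231256
"DSS+serpin1","DSS+serpin1_6",1.35729074661371
"DSS+serpin1","DSS+serpin1_7",1.51296439097861
"DSS+serpin1","DSS+serpin1_8",1.19810681911564
"DSS+serpin2","DSS+serpin2_1",1.60687453602866
"DSS+serpin2","DSS+serpin2_2",1.52547252718792
"DSS+serpin2","DSS+serpin2_3",1.35821814672329
"DSS+serpin2","DSS+serpin2_4",1.55784322343792
"DSS+serpin2","DSS+serpin2_5",1.65239173633608
"DSS+serpin2","DSS+serpin2_6",1.61953763492773
"DSS+serpin2","DSS+serpin2_7",1.29140026688463
"DSS+serpin2","DSS+serpin2_8",1.44229324010275
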