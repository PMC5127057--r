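>synthetic_serpin_1
LWHCRIDIRINWYIVRGSEMGCEGMITQEDPKIPRKCNILQISVFGDKSISVVIGLPHNGESTMPNVATANMSCKTIKKY
QMYIVDVPVMCYCVIFTSKRMIMPNCYAPELHNPHWELTGNQMKIAMLVNDRFVCAMHCAGQIRRCRMEDCDVIPVSGIR
YMKKHPEIDQNQFPDWMRTAWPMGLHSGCQHDVLVNRFEQIYTSQCYDDDCEIRVIQCSTTDQTFGQQLYLLADKRADFH
MLDRAKWVLSHLWAKHETGEFEVSRKCYHAASYCKLTYMKTTINEPLWCDLARMNFCLRDNSLECAVPYPPLQPEMMNWP
HYMREKLHALGGAVAGSVMAVKFTWCRDQEINIFHGRSWS
>synthetic_serpin_2
KHKVQWKYHCYYENETLESNRNQDLPAHIAPLFVGYTEMLCMVFKVTMTMTKVIKFPTVAPGASACHDFAVAWQGECNNQ
SESTLMASVCPTQTKHRCDFESCPQMFYEGYFYMTQQARKPQAALGPAIIGFGVITKYWACDPCKRDLNTMEECMSLRLE
GVWYWNDDVMGPRDKKQPPVPYGNRIVMGEHWCDDIHVMTEDYWDWCRFPCGYSSEYIHGLTEHVQLMGVVTAWWNPLNW
MNCKLESREMAVAMTPVIFWNCPVWACHRLLIDFLNRCHDCYKPTARAIVWITVGTSSVHTGYRQWTHFNDYPIDMCLMQ
PGNHQPYYYPNQNTQDPRPHCFHSVQIQVLAQMIAPNMNKACNDEYGKYYGAVSGVEAAAVSMENDIGCVYGHEMWSAWN
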