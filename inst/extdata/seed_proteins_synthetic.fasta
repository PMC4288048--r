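>traR_synthetic
GFKNGHPGHDTMSRSHNDLYMMIFHMQCRYKLPECYQHVQCEARPQYEYEQEPQPSWNNF
YDPKAPTCTDPWWMNESDHFCYMEWGTGPNHGRNVNCVPQHKRILPLSKTNLCIVSWVRV
EMPCTPTQGRRIKCFELHWKPAHNHVMKPGILAKAIWWQEAMHWGNPKINQMHNVIFEEG
SLAKQLEGTWNMPWHWQNRQNLKYPVINCWWHSIYRDTNAIHPCFDYHNRDESL
>traI_synthetic
RHEGMRCYKMDNAPTVGRALLAFKLHTRFRGAQMLQSEYDLWMVRNALGQYGKSAGYALI
NIEIVEVKPNHICCINTETGNCVWGLPPEVVRRECYWRHHAPQLELELLMYFYYVPDWRQ
KWIMLWWNYDAEVIKAKDQSHAKEWERIKGGILQQEARHARQDVQLGEEPRWLNAKHNMS
WIKYCPPQLWDSFYWTKHEKQHTLSCYRHHR
>luxR_seed_1
FFKNFHPPHSTYSRSHQDLCGDIFHMQCRGKTPLCPQHVQMQARPLAEIENLPQPSWILD
YDNKAPTATDPWWFNESSEFLYMHWGTGSNHGRRVNCVPQHVRILMLVKTNLIIVSWVNV
ERPCTPTPGRMIHAFELFWAPFENCVMKPVELAKAIWDQCAMNHGNPKINQMHNKIFEEG
SLDKQLEGQTMMPWHLQNIQNLKYPVITLDWHSIYRDKNIQHPKCDSNNRLESL
>luxR_seed_2
GFKNVHPAADIMQRSHSDFDMMIYHMQCYYWLPNYYQHVQCERQPQTEYEHEPQPSWNNV
YDPKAPTTTDGVWMNESDHNCEMEWGTGKNCGRCVNCVPQRKRIWPLSKTNLCIVSWLRV
EMWCTCTQGRRTKCNELHWKPAHDHVIKPMILAHAIAWQEASHAGNPKANQMHNKGREEC
SLAKCELGTCNMPWTWQNRQIFKYPVRNCWTESIYYKTNCIHPCMVYRNRDEYL
>luxR_seed_3
LFKNNGTGHRTMARVHYDLYMMPFEMQKRYKIPSCMQTVICKARTQYEYENEPLPLWNNT
YEPKAPTMTDPWWYVESDHFIYMEWGTGPDHSRNVNCVEEHWRIAMMWCMNVCIVSDVRA
EMPSTAAQPQVIIFNELHWKFAHNCQMKRPILAKAIWQQCAFHWENPKIKQMFNVIKEEG
CLAQQREGTCFMDRHWQNRNNLKLPVHLCWWHSVYRDNIAGLPRFDYHNRDELL
>luxI_seed_1
HHERMRCYKMWNASCVGRASLAFKLTSRMRGAHMVQSEADLWMVKNALDQYGPSAGYALI
NIEIVEEKPNHYTCINTTHGNCDWGLPPIVHRRECASEHHAPLLEEGLKMYFYHVDDWRQ
KWIMLWKNRDAEVLKDKDQSHMKAWERITIGILQQHARHARQDVQLGEGSRWLNAKMNMF
WLKNAPPQLWDSVYWTKHEKQFTLTCYRPHR
>luxI_seed_2
CHDSMECKKMDQANTVGRAMLEFKGITRFRLAFPYDSCYVRWMHFNALGQYGGSAGYLLK
VIEIVEVKPGHICCINLYTEIMVWRLPPEAVRRECYWRPHCPQLELELVMYFRYVPDWHQ
KWIMLWWNYHAEVRKAMEQSLAKEWERIWGGILQNEARHATFDVLLGEEYAWLNAKHIMR
QIKLCPPQCWDSFNWMKHEVQVTLSCYRHHR
>luxI_seed_3
RHKGMPCYCMDNAWTIGPALQAFKPHIAFRLAQMGQSDYDLWMVRNNLSQEGKSAGYVPI
NIEIVEEKPRHIACINMEQGHCRWGLPPEVDRRECCWSHYAPQLELECLMYFYDVPDWRQ
RWYKLEWKYHAEVIKAKDASHEQEFERIMGGIIQYEARRMRWAVHLREQPQWLNADANWS
WIKYCWPQLQQEFHWFKIIKQHRLSCVRHHR
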