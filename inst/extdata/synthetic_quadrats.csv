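"quadrat_id","area","tree_id","D","H"
"Q1",150,"QT001",0.10299,7.667
"Q1",150,"QT002",0.06512,5.754
"Q1",150,"QT003",0.09265,7.073
"Q1",150,"QT004",0.14188,8.106
"Q1",150,"QT005",0.13543,8.242
"Q1",150,"QT006",0.11945,7.99
"Q1",150,"QT007",0.09787,6.964
"Q1",150,"QT008",0.10735,7.295
"Q1",150,"QT009",0.09367,7.074
"Q1",150,"QT010",0.10265,7.36
"Q1",150,"QT011",0.07435,6.683
"Q1",150,"QT012",0.0674,5.659
"Q1",150,"QT013",0.13075,8.323
"Q1",150,"QT014",0.14429,8.921
"Q1",150,"QT015",0.15092,9.162
"Q1",150,"QT016",0.10064,7.578
"Q2",150,"QT017",0.10523,7.694
"Q2",150,"QT018",0.10328,7.248
"Q2",150,"QT019",0.08471,6.547
"Q2",150,"QT020",0.11717,7.845
"Q2",150,"QT021",0.11692,8.121
"Q2",150,"QT022",0.09428,6.858
"Q2",150,"QT023",0.12034,7.811
"Q2",150,"QT024",0.10755,7.404
"Q2",150,"QT025",0.09986,7.054
"Q2",150,"QT026",0.11993,7.762
"Q2",150,"QT027",0.09721,6.71
"Q2",150,"QT028",0.07457,6.22
"Q2",150,"QT029",0.07377,6.254
"Q2",150,"QT030",0.15161,8.454
"Q2",150,"QT031",0.1014,7.235
"Q2",150,"QT032",0.10348,7.152
"Q3",150,"QT033",0.11271,7.432
"Q3",150,"QT034",0.09804,7.2
"Q3",150,"QT035",0.08941,7.065
"Q3",150,"QT036",0.11539,8.036
"Q3",150,"QT037",0.06264,5.723
"Q3",150,"QT038",0.12554,7.631
"Q3",150,"QT039",0.06473,5.801
"Q3",150,"QT040",0.11289,7.832
"Q3",150,"QT041",0.11171,7.649
"Q3",150,"QT042",0.0974,7.24
"Q3",150,"QT043",0.11521,8.115
"Q3",150,"QT044",0.07456,6.189
"Q3",150,"QT045",0.07058,6.151
"Q3",150,"QT046",0.12052,7.99
"Q3",150,"QT047",0.09061,6.87
"Q3",150,"QT048",0.07271,6.255
"Q4",150,"QT049",0.10019,7.28
"Q4",150,"QT050",0.12388,7.931
"Q4",150,"QT051",0.0983,6.989
"Q4",150,"QT052",0.10187,7.342
"Q4",150,"QT053",0.157431,9.492382
"Q4",150,"QT054",0.11454,7.372
"Q4",150,"QT055",0.06695,6.107
"Q4",150,"QT056",0.14737,9.018
"Q4",150,"QT057",0.10437,6.846
"Q4",150,"QT058",0.09256,6.632
"Q4",150,"QT059",0.12692,7.887
"Q4",150,"QT060",0.07984,6.33
"Q4",150,"QT061",0.11752,7.862
"Q4",150,"QT062",0.11744,7.722
"Q4",150,"QT063",0.1452,8.766
"Q4",150,"QT064",0.12654,8.451
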