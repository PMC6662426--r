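"tree_id","age","ring_D"
"T01",1,0.00489
"T01",2,0.01161
"T01",3,0.02032
"T01",4,0.03077
"T01",5,0.04224
"T01",6,0.05365
"T01",7,0.06395
"T01",8,0.07246
"T01",9,0.07899
"T01",10,0.08371
"T01",11,0.087
"T02",1,0.00529
"T02",2,0.01255
"T02",3,0.02195
"T02",4,0.03324
"T02",5,0.04564
"T02",6,0.05797
"T02",7,0.0691
"T02",8,0.07829
"T02",9,0.08534
"T02",10,0.09045
"T02",11,0.094
"T03",1,0.00557
"T03",2,0.01321
"T03",3,0.02312
"T03",4,0.03501
"T03",5,0.04806
"T03",6,0.06105
"T03",7,0.07277
"T03",8,0.08245
"T03",9,0.08988
"T03",10,0.09526
"T03",11,0.099
"T04",1,0.00585
"T04",2,0.01388
"T04",3,0.02428
"T04",4,0.03678
"T04",5,0.05049
"T04",6,0.06414
"T04",7,0.07645
"T04",8,0.08662
"T04",9,0.09442
"T04",10,0.10007
"T04",11,0.104
"T05",1,0.00613
"T05",2,0.01455
"T05",3,0.02545
"T05",4,0.03855
"T05",5,0.05292
"T05",6,0.06722
"T05",7,0.08013
"T05",8,0.09078
"T05",9,0.09896
"T05",10,0.10488
"T05",11,0.109
"T06",1,0.00652
"T06",2,0.01548
"T06",3,0.02709
"T06",4,0.04102
"T06",5,0.05632
"T06",6,0.07154
"T06",7,0.08527
"T06",8,0.09661
"T06",9,0.10531
"T06",10,0.11162
"T06",11,0.116
"T07",1,0.00709
"T07",2,0.01682
"T07",3,0.02942
"T07",4,0.04456
"T07",5,0.06117
"T07",6,0.0777
"T07",7,0.09262
"T07",8,0.10494
"T07",9,0.11439
"T07",10,0.12124
"T07",11,0.126
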