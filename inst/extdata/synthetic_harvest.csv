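"tree_id","D","H","wt_above","wt_below","wt_leaf","leaf_excluded"
"T01",0.087,6.9,22.5464,10.0636,2.8654,FALSE
"T02",0.094,7.2,26.7806,11.0092,3.394,FALSE
"T03",0.099,7.5,30.7995,12.5447,4.1234,FALSE
"T04",0.104,7.7,34.6685,15.4389,4.1654,FALSE
"T05",0.109,7.9,37.4269,16.3364,4.7457,FALSE
"T06",0.116,8.2,45.6989,19.684,5.1696,FALSE
"T07",0.126,8.6,53.5723,23.0569,NA,TRUE
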