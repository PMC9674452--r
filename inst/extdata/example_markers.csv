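"individual_id","population_id","transect_position","L01","L02","L03","L04","L05","L06","L07","L08"
"pop01_i01","pop01",13.1962034502067,1,1,1,0,0,0,0,1
"pop01_i02","pop01",7.65602603321895,1,1,1,0,1,0,0,1
"pop01_i03","pop01",5.01563019468449,0,1,1,1,0,0,0,0
"pop01_i04","pop01",9.20002970960923,1,1,1,1,0,1,1,0
"pop02_i01","pop02",5.96262322040275,1,1,1,1,0,0,0,1
"pop02_i02","pop02",2.09902661852539,1,0,1,1,0,0,0,1
"pop02_i03","pop02",1.18645194335841,1,0,1,1,0,0,0,1
"pop02_i04","pop02",8.2533229154069,1,0,1,1,1,0,0,1
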