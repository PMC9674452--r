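8,8,2,4,4
example dominant-marker export,,pop01,pop02
sample,pop,L01,L02,L03,L04,L05,L06,L07,L08
pop01_i01,pop01,1,1,1,0,0,0,0,1
pop01_i02,pop01,1,1,1,0,1,0,0,1
pop01_i03,pop01,0,1,1,1,0,0,0,0
pop01_i04,pop01,1,1,1,1,0,1,1,0
pop02_i01,pop02,1,1,1,1,0,0,0,1
pop02_i02,pop02,1,0,1,1,0,0,0,1
pop02_i03,pop02,1,0,1,1,0,0,0,1
pop02_i04,pop02,1,0,1,1,1,0,0,1
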