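region,population,census_size,ppl,h_en,n_per_family,latitude,longitude
Luxembourg,1,67,94.2,0.338,6.4,49.605,6.058
Luxembourg,2,8000,92.3,0.378,5.7,49.605,6.060
Luxembourg,3,59,90.4,0.356,5.0,49.609,6.026
Luxembourg,4,1000,96.2,0.361,6.0,49.597,6.067
Luxembourg,5,22000,98.1,0.348,6.5,49.572,5.951
Luxembourg,6,2400,96.2,0.364,5.9,49.611,6.026
Luxembourg,7,3430,84.6,0.327,5.9,49.602,5.980
Luxembourg,8,11,94.2,0.345,6.0,49.614,6.018
Luxembourg,9,210,96.2,0.331,6.1,49.621,6.018
Luxembourg,10,14800,94.2,0.342,5.6,49.5477,5.9033
Luxembourg,11,8000,100,0.377,6.0,49.5479,5.9026
Luxembourg,12,200,94.2,0.350,6.3,49.570,6.043
Luxembourg,13,5100,92.3,0.339,6.1,49.571,6.041
Luxembourg,14,15,71.2,0.287,5.8,49.490,6.001
Luxembourg,15,900,96.2,0.373,6.5,49.489,6.000
Germany,16,4150,96.2,0.329,5.4,49.682,6.708
Germany,17,200,96.2,0.347,5.6,49.682,6.710
Germany,18,2700,90.4,0.302,5.6,49.709,6.706
Germany,19,5000,90.4,0.357,6.6,49.706,6.703
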