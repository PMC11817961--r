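locus,na,ne,ho,he,shannon,pic
GW03-1,36,20.027,0.943,0.950,3.211,0.948
GW03-7,39,11.526,0.800,0.913,2.941,0.908
GW07-1,46,30.071,0.508,0.967,3.608,0.966
GW07-4,41,15.989,0.689,0.937,3.119,0.934
GW02-3,15,6.229,1.000,0.839,2.136,0.823
GW06-6,32,9.492,1.000,0.895,2.796,0.889
GW13-5,24,13.445,1.000,0.926,2.779,0.921
GW13-7,38,8.086,0.876,0.876,2.765,0.869
GW01-3,25,4.736,0.933,0.789,2.275,0.778
GW05-2,44,23.339,0.816,0.957,3.440,0.956
GW06-3,22,11.575,0.990,0.914,2.652,0.907
GW11-7,24,8.136,0.541,0.877,2.460,0.866
GW06-2,64,31.729,0.901,0.968,3.786,0.968
GW06-7,42,25.057,0.771,0.960,3.443,0.959
GW09-6,37,15.320,0.750,0.935,3.083,0.931
GW12-4,33,14.300,0.924,0.930,2.998,0.926
GW01-5,27,13.554,0.240,0.926,2.876,0.922
GW01-6,18,7.172,0.500,0.861,2.185,0.846
GW02-6,39,21.000,0.724,0.952,3.296,0.950
GW13-3,25,16.185,0.699,0.938,2.933,0.935
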