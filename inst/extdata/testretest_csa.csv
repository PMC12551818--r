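mouse,side,csa_test_mm2,csa_retest_mm2,rel_diff_pct
m1,left,0.305,0.323,-5.825
m1,right,0.311,0.317,-1.942
m2,left,0.311,0.256,19.355
m2,right,0.208,0.183,12.500
m3,left,0.232,0.208,11.111
m3,right,0.146,0.134,8.696
m4,left,0.330,0.385,-15.385
m4,right,0.305,0.281,8.333
m5,left,0.238,0.269,-12.048
m5,right,0.195,0.195,0.000
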