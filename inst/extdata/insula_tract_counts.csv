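gyrus_a,gyrus_b,patient,control_mean
LSAG,LSMG,2528,382
LSAG,LSPG,97,31
LSAG,LLAG,0,19
LSAG,LLPG,2,34
LSMG,LSPG,3122,776
LSMG,LLAG,47,119
LSMG,LLPG,0,5
LSPG,LLAG,2392,800
LSPG,LLPG,0,128
LLAG,LLPG,22,391
RSAG,RSMG,541,543
RSAG,RSPG,3648,74
RSAG,RLAG,156,98
RSAG,RLPG,0,74
RSMG,RSPG,2554,632
RSMG,RLAG,335,328
RSMG,RLPG,1,96
RSPG,RLAG,3359,939
RSPG,RLPG,137,51
RLAG,RLPG,714,313
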