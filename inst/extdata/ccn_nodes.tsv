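name	self_degrading
Cln3	1
MBF	0
SBF	0
Cln1,2	1
Cdh1	0
Swi5	1
Cdc20&Cdc14	1
Clb5,6	0
Sic1	0
Clb1,2	0
Mcm1/SFF	1
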