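source	target	weight
Cln3	MBF	1
Cln3	SBF	1
SBF	Cln1,2	1
MBF	Clb5,6	1
Cdc20&Cdc14	Swi5	1
Cdc20&Cdc14	Cdh1	1
Cdc20&Cdc14	Sic1	1
Clb5,6	Mcm1/SFF	1
Clb5,6	Clb1,2	1
Swi5	Sic1	1
Clb1,2	Mcm1/SFF	1
Clb1,2	Cdc20&Cdc14	1
Mcm1/SFF	Cdc20&Cdc14	1
Mcm1/SFF	Swi5	1
Mcm1/SFF	Clb1,2	1
Cln1,2	Sic1	-1
Cln1,2	Cdh1	-1
Clb5,6	Sic1	-1
Clb5,6	Cdh1	-1
Cdc20&Cdc14	Clb5,6	-1
Cdc20&Cdc14	Clb1,2	-1
Sic1	Clb5,6	-1
Sic1	Clb1,2	-1
Cdh1	Clb1,2	-1
Clb1,2	MBF	-1
Clb1,2	SBF	-1
Clb1,2	Sic1	-1
Clb1,2	Swi5	-1
Clb1,2	Cdh1	-1
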