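snp	effect_allele	other_allele	beta_exp	se_exp	beta_out	se_out	gene
rs8168562	T	A	0.12082755121402443	0.01	0.14137589349575119	0.080000000000000002	GENE01
rs3348434	T	A	-0.10234896576497704	0.01	-0.18239000060760582	0.080000000000000002	GENE02
rs2097428	G	T	0.048218194495420905	0.01	0.22563775223853397	0.080000000000000002	GENE03
rs6914588	T	A	0.067144029811024658	0.01	0.080182831538704008	0.080000000000000002	GENE04
rs1332770	G	A	0.10219797129509971	0.01	0.15311952147510635	0.080000000000000002	GENE05
rs9348155	A	C	-0.033267049549613147	0.01	0.031088433512723924	0.080000000000000002	GENE06
rs3674913	A	T	-0.090609972146339715	0.01	-0.23927764979305421	0.080000000000000002	GENE07
rs0789612	A	T	-0.14193138906266539	0.01	-0.21638072685004195	0.080000000000000002	GENE08
rs1162540	C	A	0.062825153239537024	0.01	0.23545829349660302	0.080000000000000002	GENE09
rs3153122	A	G	0.10550482384860516	0.01	0.15999589846251883	0.080000000000000002	GENE10
rs5010122	T	G	0.030771323386579751	0.01	0.07853062223719133	0.080000000000000002	GENE11
rs6035771	G	C	0.11994257218437269	0.01	0.18971795021626658	0.080000000000000002	GENE12
rs5749262	G	A	0.060046256105415523	0.01	0.055796602721772337	0.080000000000000002	GENE13
rs3772966	A	T	0.14030922009376809	0.01	0.007972857448443435	0.080000000000000002	GENE14
rs5435564	C	A	-0.049998581297695632	0.01	-0.2605304306294145	0.080000000000000002	GENE15
rs7030101	T	A	0.076385210924781857	0.01	0.044265202995817737	0.080000000000000002	GENE16
rs0106805	C	T	0.10087658554082736	0.01	0.27037961267432753	0.080000000000000002	GENE17
rs4408095	A	G	0.030155689790844917	0.01	0.13493238800592405	0.080000000000000002	GENE18
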