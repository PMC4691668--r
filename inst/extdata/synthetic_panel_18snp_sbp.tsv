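snp	effect_allele	other_allele	beta_exp	se_exp	beta_out	se_out	gene
rs5658420	T	C	0.12524062014650555	0.01	0.20178516187972498	0.080000000000000002	GENE01
rs7632548	G	A	0.091848986216355122	0.01	0.095729044278464751	0.080000000000000002	GENE02
rs1199061	T	G	0.09684806111035868	0.01	0.11848133652304307	0.080000000000000002	GENE03
rs7420543	G	A	0.094796193346846844	0.01	0.044289301032818126	0.080000000000000002	GENE04
rs1458324	G	T	-0.13143698808504267	0.01	-0.34955361890913333	0.080000000000000002	GENE05
rs5054869	T	A	0.095552780644502497	0.01	0.099451094771032769	0.080000000000000002	GENE06
rs6352354	C	G	0.14679203893290832	0.01	0.21081646334145629	0.080000000000000002	GENE07
rs7181522	A	T	0.046620848572347315	0.01	0.069962805099133732	0.080000000000000002	GENE08
rs0599281	G	C	0.11380737063474954	0.01	0.076521993341981537	0.080000000000000002	GENE09
rs9338855	T	G	0.10403903708094731	0.01	0.10908473735195737	0.080000000000000002	GENE10
rs1146241	A	T	-0.086591152418404815	0.01	-0.14620564328308183	0.080000000000000002	GENE11
rs5844683	G	T	-0.15380244231782852	0.01	-0.23762306086864032	0.080000000000000002	GENE12
rs1594833	T	G	-0.11506647877162322	0.01	-0.27194001180042321	0.080000000000000002	GENE13
rs0337265	T	G	0.033098635098431257	0.01	0.36103854757290987	0.080000000000000002	GENE14
rs2503838	C	A	0.09085597376106308	0.01	0.29598573035419945	0.080000000000000002	GENE15
rs2921975	C	G	0.14145461026579143	0.01	0.11604821624726108	0.080000000000000002	GENE16
rs2939380	C	G	0.077457836016546933	0.01	0.044817060147626944	0.080000000000000002	GENE17
rs3218052	C	A	-0.077524743515532457	0.01	0.029459783726771674	0.080000000000000002	GENE18
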