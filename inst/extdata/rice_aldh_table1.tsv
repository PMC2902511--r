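family	name	locus	function	localization_raw	localization	cds_bp	n_aa	mw_kda
2	OsALDH2B1	Os06g15990	Aldehyde dehydrogenase	Mitochondrion	Mitochondrion	1650	549	59.3
2	OsALDH2B2	Os06g39230	Aldehyde dehydrogenase	Cytosol	Cytosol	1581	526	56.4
2	OsALDH2B5	Os02g49720	Aldehyde dehydrogenase	Mitochondrion	Mitochondrion	1662	553	58.9
2	OsALDH2C1	Os01g40870	Aldehyde dehydrogenase	Cytosol	Cytosol	1524	507	54.2
2	OsALDH2C4	Os01g40860	aldehyde dehydrogenase (NAD) coniferyl-aldehyde dehydrogenase	Cytosol	Cytosol	1509	502	54.2
3	OsALDH3B1	Os04g45720	Variable substrate ALDH			1500	499	54.3
3	OsALDH3E1	Os02g43194	aldehyde dehydrogenase [NAD(P)+]	Chloroplast	Chloroplast	1464	487	54.5
3	OsALDH3E2	Os02g43280	Variable substrate ALDH	Chloroplast	Chloroplast	1476	491	54.6
3	OsALDH3H1	Os12g07810	aldehyde dehydrogenase [NAD(P)+]	endoplasmic reticulum, membrane, vacuole	Endoplasmic reticulum, membrane, vacuole	1455	484	52.4
3	OsALDH3H2	Os11g08300	Variable substrate ALDH			1449	482	52.5
5	OsALDH5F1	Os02g07760	SSADH, oxidoreductase activity, acting on the aldehyde or oxo group of donors, NAD or NADP as acceptor	Mitochondrion	Mitochondrion	1584	527	56.1
6	OsALDH6B2	Os07g09060	MM-ALDH	Mitochondrion	Mitochondrion	1605	534	57.2
7	OsALDH7B6	Os09g26880	Antiquitin			1530	509	54.5
10	OsALDH10A5	Os04g39020	BADH			1518	505	54.6
10	OsALDH10A8	Os08g32870	BADH	Chloroplast, plastids	Chloroplast, plastids	1512	503	54.7
11	OsALDH11A3	Os08g34210	GAPN	Cytoplasm	Cytoplasm	1500	499	53.4
12	OsALDH12A1	Os05g45960	P5CDH	Mitochondrion	Mitochondrion	1653	550	60.5
12	OsALDH12B1	Os12g40440	P5CDH	Mitochodrion	Mitochondrion	2427	808	91.0
18	OsALDH18B1	Os05g38150	P5CS			2151	716	77.7
18	OsALDH18B2	Os01g62900	P5CS			2208	735	79.5
22	OsALDH22A1	Os07g48920	Aldehyde dehydrogenase (NAD)	Secretory pathway	Secretory pathway	1794	597	66.0
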