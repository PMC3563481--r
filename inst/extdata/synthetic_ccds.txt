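#chromosome	nc_accession	gene	gene_id	ccds_id	ccds_status	cds_strand	cds_from	cds_to	cds_locations	match_type
1	NC_000001.10	GENEA	101	CCDS1.1	Public	+	100	599	[100-199, 300-349, 500-599]	Identical
1	NC_000001.10	GENEB	102	CCDS2.1	Public	-	150	249	[150-249]	Identical
1	NC_000001.10	GENEC	103	CCDS3.1	Withdrawn	+	-	-	-	Identical
2	NC_000002.11	GENED	104	CCDS4.1	Public	+	0	49	[0-49]	Identical
2	NC_000002.11	GENEE	105	CCDS5.1	Reviewed, update pending	+	700	799	[700-799]	Identical
2	NC_000002.11	GENEF	106	CCDS6.1	Public	-	0	49	[0-49]	Identical
X	NC_000023.10	GENEG	107	CCDS7.1	Public	+	5	60	[abc-def]	Identical
3	NC_000003.11	GENEH	108	CCDS8.1	Public	+	10	49	[10-19, 40-49]	Identical
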