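# PRT assay and Southern-probe amplicons (hg18 / GRCh36 coordinates,
# 1-based fully-closed; length_bp is the published amplicon length)
id	role	chrom	start	end	length_bp	type	fwd_primer	rev_primer
HDLBP	probe	chr2	241855412	241860011	4600	TUF	GAGCTCATCCTCCACTTGGG	GAACTTGGTGAGAAGTGCGG
HDAC4	probe	chr2	239860758	239863570	2813	TUF	AGGTGCTAGATTTGGACGGG	GTGTGTGTTAGGGGGTCAGG
CAPN10	probe	chr2	241173030	241175779	2750	TUF	ATCTGGCTACAGGCATGGGC	GAGAGCCCAGAAGTTCCAGC
PSCDBP	probe	chr2	158003567	158006035	2469	Non-TUF	GAGGCAATCACATGAGCAGG	CTGCTAAGTGGATGAATGGTGG
MARCH7	probe	chr2	160329568	160332075	2508	Non-TUF	GGGAAATATGGGTTGGGAAACTG	ATGGTCTCCGTCTTCTTCGG
RBMS1	probe	chr2	160889938	160892713	2776	Non-TUF	AGTAAGGAGATGAGGGGTGG	ACAGGTTTTGGTGGGAGAGG
2n13	test	chr2	241151005	241151733	729	TUF	GCAGACTAATGGGGATGAGG	GCCTATCTGGAAAAATAGAC
2n13	reference	chr13	31949825	31950179	355	Non-TUF	GCAGACTAATGGGGATGAGG	GCCTATCTGGAAAAATAGAC
8n6	test	chr8	142286472	142286937	466	TUF	TTGAGTCAGCCACAGAGG	CCTGGTGACAGAATGACC
8n6	reference	chr6	89689978	89690367	390	Non-TUF	TTGAGTCAGCCACAGAGG	CCTGGTGACAGAATGACC
8n3	test	chr8	145234022	145234464	443	TUF	GCTTCATCCAGCTTCAACC	AGCAAAGTGACACTCAGTGC
8n3	reference	chr3	134693119	134693550	432	Non-TUF	GCTTCATCCAGCTTCAACC	AGCAAAGTGACACTCAGTGC
2n1	test	chr2	241707017	241707258	242	TUF	CACCCCAGTGAGTAAGCTGC	AGGGTGATCGCTTCTGACC
2n1	reference	chr1	37721785	37722026	242	Non-TUF	CACCCCAGTGAGTAAGCTGC	AGGGTGATCGCTTCTGACC
5nX	test	chr5	179593910	179594270	361	TUF	ATCTAGGCTCAGGAGAGAG	TAAACATCTTAAAATGGCCT
5nX	reference	chrX	63694585	63694959	375	Non-TUF	ATCTAGGCTCAGGAGAGAG	TAAACATCTTAAAATGGCCT
9n14	test	chr9	139562111	139562372	262	TUF	CAGAGAGCAACCTGGCTC	CTGCCTCCTTGTTTGGC
9n14	reference	chr14	94217995	94218256	262	Non-TUF	CAGAGAGCAACCTGGCTC	CTGCCTCCTTGTTTGGC
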