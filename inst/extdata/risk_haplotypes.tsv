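hap_id	chrom	start_bp	end_bp	length_mb_printed	length_discrepant	carriers	fp_sets	fp_sets_printed	main_fp	n_main_fp	diagnoses	note
1.1	1	44527042	48054945	3.53	FALSE	12,6,19	B;A/B/C/D;A/B/C	B;A/B/C/D;A/B/C	B	3	TS,OCD_probable,ADHD_probable;TS;TS	.
2.1	2	13000487	15987485	2.99	FALSE	12,6,9	B;A/B/C/D;A/B/C	B;A/B/C/D;B	B	3	TS,OCD_probable,ADHD_probable;TS;TS,ADHD_probable	carrier 9 FP set follows the carrier matrix (A/B/C); source table prints B
2.2	2	211041963	214017954	2.98	FALSE	7,3,6,19	A/B;D;A/B/C/D;A/B/C	A/B;D;A/B/C/D;A/B	A/B	3	TS,ADHD;TS;TS;TS	carrier 19 FP set follows the carrier matrix (A/B/C); source table prints A/B
4.1	4	154028117	164629683	10.62	TRUE	2,1,6	D/F;C/D;A/B/C/D	D/F;C/D;A/B/C/D	D	3	TS;TS;TS	printed length 10.62 Mb disagrees with end-start (10.60 Mb)
4.2	4	164642592	168832405	4.19	FALSE	2,3,1	D/F;D;C/D	D/F;D;C/D	D	3	TS;TS;TS	.
5.1	5	107466596	110400753	2.93	FALSE	10,7,12	B;A/B;B	B;A/B;B	B	3	TS,ADHD_probable;TS,ADHD;TS,OCD_probable,ADHD_probable	.
6.1	6	11239710	15065694	3.83	FALSE	1,15,19	C/D;C;A/B/C	C/D;C;A/B/C	C	3	TS;TS,ADHD;TS	.
9.1	9	101864325	106732943	4.87	FALSE	7,11,15,6	A/B;B;C;A/B/C/D	A/B;A/B;C;A/B/C/D	A/B	3	TS,ADHD;TS,ADHD;TS,ADHD;TS	second carrier id ambiguous in source rendering; 11 is the only reading consistent with fourteen distinct carriers overall
9.2	9	130138362	132407549	2.27	FALSE	7,13,8	A/B;B;A/B/C	A/B;B;A/B/C	B	3	TS,ADHD;TS,ADHD;TS,ADHD	.
18.1	18	66447780	69214658	2.77	FALSE	7,12,19	A/B;B;A/B/C	A/B;B;A/B/C	B	3	TS,ADHD;TS,OCD_probable,ADHD_probable;TS	.
20.1	20	9153822	12651396	3.55	TRUE	5,1,6	C/E;C/D;A/B/C/D	C/E;C/D;A/B/C/D	C	3	CMVT,ADHD_probable;TS;TS	printed length 3.55 Mb disagrees with end-start (3.50 Mb)
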