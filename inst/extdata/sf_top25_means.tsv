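miRNA	mean_mcf10a	mean_mcf7	mean_mda	trend_mcf7	trend_mda
hsa-mir-6087	5847.1	1124.3	705.3	D	D
hsa-mir-21	362.6	1173.3	1155.5	U	U
hsa-mir-1246	484.6	83.8	32.0	D	D
hsa-mir-3687	460.6	34.9	8.2	D	D
hsa-mir-100	13.1	0.0	483.4	D	U
hsa-mir-612	450.5	1.6	3.0	D	D
hsa-mir-7704	296.4	41.8	20.2	D	D
hsa-let-7f-1	54.0	90.6	184.7	U	U
hsa-let-7f-2	32.1	86.0	173.2	U	U
hsa-let-7g	20.4	84.8	170.6	U	U
hsa-mir-3064	196.6	46.3	8.8	D	D
hsa-mir-1291	88.0	147.6	14.9	U	D
hsa-let-7i	21.2	62.3	140.3	U	U
hsa-mir-5047	163.8	14.5	1.2	D	D
hsa-mir-622	54.6	74.2	16.8	U	D
hsa-mir-19b-1	14.0	60.1	50.6	U	U
hsa-mir-20a	15.1	53.2	51.0	U	U
hsa-mir-222	6.5	0.0	105.5	D	U
hsa-mir-30a	5.2	0.8	91.1	D	U
hsa-mir-148a	47.4	32.4	4.0	D	D
hsa-mir-7161	74.7	1.9	1.2	D	D
hsa-mir-24-1	27.1	10.2	40.3	D	U
hsa-mir-1248	66.8	4.5	5.3	D	D
hsa-mir-3607	57.0	10.8	4.3	D	D
hsa-mir-221	8.5	0.0	59.7	D	U
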