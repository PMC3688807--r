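# pd2loop alphabet v1
n_letters	27
meta_trained_on	pd2loop synthetic fixture family v1
meta_seed	7
letter	1	1.53373380251	1.57131821836	1.16578148569
letter	2	1.5482126737	1.598176277	0.914490584577
letter	3	1.55000059066	2.04701547847	1.9276234623
letter	4	1.56397298583	1.63892548225	-2.3902718135
letter	5	1.56835471803	2.15240362683	1.2479316079
letter	6	1.56927506933	2.32979285532	0.150723807118
letter	7	1.57536263853	1.56844966902	1.49407155597
letter	8	1.5770756086	2.20600004404	0.651827237857
letter	9	1.57802626545	1.61205187729	-0.867764950027
letter	10	1.5827556739	1.63538872045	0.854744318854
letter	11	1.5863442991	1.59024974205	0.480244565624
letter	12	1.60085025746	1.54731634624	0.930839785581
letter	13	1.60341725523	1.71156412647	3.0698290198
letter	14	1.61958566943	1.566226964	0.86260736398
letter	15	1.62778397074	2.15135234631	2.53546381081
letter	16	2.09626108946	1.58266323671	-2.6569268386
letter	17	2.15540588844	1.57318910624	-0.00256445369205
letter	18	2.15643748036	2.16319525186	-2.91006415133
letter	19	2.16523335348	2.3340202588	3.01189602893
letter	20	2.18347545477	1.62008221763	-3.09546087023
letter	21	2.18373171375	2.14404001384	-2.43367463098
letter	22	2.18973843993	1.55303071277	-2.25615832419
letter	23	2.20499739574	2.05818795942	-2.10887931349
letter	24	2.20649539881	2.20924065325	-2.8200188642
letter	25	2.20980433737	2.44745097709	2.61516439097
letter	26	2.27346285936	1.80819142631	-1.70736911133
letter	27	2.30027261041	1.61802917153	0.495530488073
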