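chrom	start	end	length	score
1	82955709	82956371	663	306.0
7	1194442	1195252	811	286.97
1	76438827	76439515	689	251.83
5	4911834	4912728	895	236.06
5	4907997	4908831	835	235.12
9	4315702	4316286	585	230.55
1	89187456	89187990	535	214.65
8	61869092	61869619	528	201.54
3	59054967	59055546	580	188.78
9	58915814	58916418	605	184.69
6	41195995	41196596	602	173.86
2	46987902	46988604	703	173.8
2	48205156	48205766	611	173.8
12	6609432	6610083	652	173.8
12	64009107	64009667	561	173.51
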