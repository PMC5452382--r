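chr1	5922	6227
chr1	9388	10121
chr1	24265	24471
chr1	26807	27432
chr1	29174	29479
chr1	38882	39678
chr1	56432	56951
chr1	58033	58495
chr1	59029	59215
chr1	62597	62873
chr1	63813	64238
chr1	81866	82511
chr1	105673	106283
chr1	109861	110714
chr1	112063	112244
chr1	112860	113313
chr1	113617	114233
chr1	115763	117271
chr1	120009	120621
chr1	120854	123679
chr1	125515	126102
chr1	129372	130228
chr1	131073	131315
chr1	141881	142181
chr1	142698	142918
chr1	144884	146335
chr1	155529	156121
chr1	158081	158903
chr1	163973	164124
chr1	167044	168448
chr1	173691	174323
chr1	175929	176556
chr1	179715	180284
chr1	180474	181082
chr1	184917	185217
chr1	190568	190729
chr1	193809	194136
chr1	194203	194443
chr1	198084	198718
chr2	9408	10172
chr2	19426	20217
chr2	20925	21840
chr2	29026	29576
chr2	33928	35200
chr2	36491	37961
chr2	39813	40690
chr2	43305	43627
chr2	50449	51205
chr2	60167	61377
chr2	73980	75151
chr2	76467	77302
chr2	83623	84331
chr2	86487	87316
chr2	87848	88598
chr2	93547	94164
chr2	96098	97503
chr2	98034	99613
chr1	21636	21941
chr1	2625	3320
chr1	191353	191691
chr1	105029	105507
chr1	32051	32405
chr1	76340	76494
chr2	99371	99893
chr1	145708	145937
chr2	7942	8151
chr2	38701	39366
chr2	46979	47380
chr1	89142	89413
chr1	165957	166174
chr1	33549	33759
chr2	30343	30741
chr1	146320	146863
chr1	176368	176903
chr2	20588	20886
chr2	5616	6220
chr1	43633	43824
chr1	170931	171215
chr2	71283	71800
chr1	156148	156486
chr1	106388	106989
chr2	95014	95326
chr1	160708	161324
chr2	85602	85854
chr2	38823	39130
chr1	101587	101837
chr2	67893	68461
chr1	151130	151416
chr1	183403	183878
chr1	41778	42305
chr2	99939	100000
chr1	168058	168261
chr1	152951	153631
chr1	115530	115876
chr2	52503	53126
chr1	116665	117338
chr1	177060	177605
chr1	117054	117678
chr1	36293	36993
chr2	82790	83040
chr1	183228	183779
chr2	15603	15943
chr1	197182	197618
chr1	176366	176708
chr1	88717	88875
chr2	33825	34282
chr1	57887	58215
chr2	30313	30984
chr1	172349	172836
chr2	13588	14223
chr1	87650	88181
chr1	73612	74120
chr2	10351	10893
chr2	50972	51651
chr1	70645	71259
chr1	139185	139840
chr1	83907	84403
chr1	133510	134073
chr1	20944	21571
chr2	11574	11884
chr1	86394	86568
chr1	128580	128939
chr1	128420	128640
chr1	56512	57026
chr2	53739	54402
chr2	20233	20470
chr1	46092	46541
chr1	120082	120448
chr2	83290	83975
chr1	85978	86381
chr2	46748	47219
chr1	60195	60875
chr1	58072	58616
chr1	142431	143112
chr2	61586	61738
chr1	70928	71362
chr2	53868	54349
chr1	90765	91150
chr1	41905	42073
chr1	69734	70131
chr1	104763	105215
chr1	148511	148904
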