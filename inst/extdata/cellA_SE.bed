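chr1	5985	6290
chr1	8621	8995
chr1	9480	10213
chr1	11424	12250
chr1	17294	18738
chr1	19929	20785
chr1	23292	23742
chr1	24677	25545
chr1	26358	26534
chr1	27055	27680
chr1	28986	29291
chr1	32005	33681
chr1	37597	38465
chr1	38988	39784
chr1	40188	41105
chr1	43087	43573
chr1	45626	46921
chr1	53109	53882
chr1	56334	56853
chr1	63796	64221
chr1	67952	68548
chr1	70555	71995
chr1	73022	73454
chr1	76222	76509
chr1	81647	82292
chr1	85551	87252
chr1	87777	88072
chr1	88241	88408
chr1	88570	90195
chr1	96369	96548
chr1	99943	100815
chr1	105839	106449
chr1	108309	108500
chr1	109802	110655
chr1	112831	113284
chr1	115856	117364
chr1	119802	120414
chr1	120812	123637
chr1	128443	128800
chr1	131176	131418
chr1	134408	135307
chr1	141819	142119
chr1	143901	144525
chr1	152209	152505
chr1	156241	157931
chr1	158042	158864
chr1	162313	162935
chr1	165665	166656
chr1	169981	170813
chr1	171128	171339
chr1	172265	173362
chr1	179707	180276
chr1	181504	182044
chr1	185908	186311
chr1	191122	191815
chr1	192405	193757
chr1	198072	198706
chr2	313	742
chr2	3324	4005
chr2	6644	7539
chr2	8119	8585
chr2	9341	10105
chr2	15371	16055
chr2	24711	25309
chr2	28060	28622
chr2	29156	29706
chr2	30112	31372
chr2	35089	35434
chr2	35729	36305
chr2	36491	37961
chr2	39893	40770
chr2	43437	43759
chr2	45012	45421
chr2	50673	51429
chr2	57994	58833
chr2	63636	65225
chr2	70567	71101
chr2	71853	72046
chr2	76276	77111
chr2	78177	78419
chr2	83567	84275
chr2	86319	87148
chr2	89152	90031
chr2	90413	90637
chr2	91729	92447
chr2	93572	94189
chr2	99802	100000
chr1	21794	22171
chr1	109541	110230
chr1	116940	117541
chr1	110592	110784
chr2	38	700
chr1	137671	138276
chr1	47228	47903
chr1	39961	40462
chr2	6478	6676
chr2	89489	89697
chr1	7889	8303
chr1	157628	157999
chr1	194024	194452
chr1	33742	34258
chr1	66828	67084
chr1	182769	183096
chr1	169408	169785
chr1	176587	177282
chr1	54062	54302
chr2	9492	9749
chr1	167991	168586
chr2	45040	45427
chr1	168100	168273
chr2	29492	30170
chr2	18898	19393
chr2	6573	7157
chr2	61190	61490
chr1	198128	198561
chr1	173172	173809
chr1	134800	135222
chr2	10328	10929
chr2	2607	3304
chr2	96771	96988
chr1	84893	85077
chr2	20344	21042
chr1	189216	189529
chr2	65755	66385
chr1	61038	61371
chr1	98601	98904
chr1	115512	115781
chr2	2095	2390
chr1	144515	144757
chr1	48881	49343
chr1	119747	120410
chr2	37928	38271
chr2	1563	2250
chr1	35196	35682
chr2	32506	32688
chr1	36434	36933
chr2	72300	72958
chr2	41630	41911
chr1	191808	192036
chr1	14516	14886
chr2	86304	86968
chr1	154597	155233
chr1	43664	43860
chr1	158856	159490
chr1	73642	74036
chr2	99896	100000
chr2	47191	47821
chr1	167801	168405
chr1	177267	177909
chr1	90799	91283
chr2	99833	100000
chr2	60123	60684
chr1	160338	161003
chr1	8037	8612
chr1	49935	50408
chr1	12480	13127
chr1	111583	111925
chr1	195442	196079
chr1	60654	61181
chr2	53802	54484
chr1	118922	119373
chr1	137054	137540
chr1	102826	103414
chr1	145975	146394
chr1	154092	154692
chr2	25522	25818
chr1	154484	154695
chr1	158720	158934
chr1	111802	112265
chr1	5067	5564
chr1	113103	113260
chr2	91148	91305
chr1	30704	30924
chr1	142066	142654
chr1	58865	59410
chr1	124251	124804
chr2	22982	23666
chr1	37104	37516
chr1	159256	159892
chr1	72885	73403
chr1	162549	163201
chr1	120614	121023
chr2	95417	95648
chr1	198621	199066
chr1	48121	48737
chr1	181330	181566
chr1	10083	10362
chr2	28361	28709
chr1	131112	131635
chr2	33709	33937
chr1	147806	148255
chr2	15637	15955
chr1	44806	45317
chr1	114860	115528
chr1	183184	183424
chr2	59928	60486
chr1	113562	114023
chr2	52300	52958
chr1	155839	156034
chr2	37658	37935
chr1	188531	188882
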