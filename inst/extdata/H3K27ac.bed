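chr1	5097	5740
chr1	6663	6859
chr1	8445	8819
chr1	9390	10123
chr1	11238	12064
chr1	17256	18700
chr1	20023	20879
chr1	21493	22109
chr1	26203	26379
chr1	26854	27479
chr1	29125	29430
chr1	31963	33639
chr1	38906	39702
chr1	39981	40261
chr1	40291	41208
chr1	43086	43572
chr1	45762	47057
chr1	48968	49763
chr1	52939	53712
chr1	58092	58554
chr1	59139	59325
chr1	60323	61634
chr1	62583	62859
chr1	63876	64301
chr1	68171	68767
chr1	76215	76502
chr1	81743	82388
chr1	82890	83588
chr1	83724	84615
chr1	85429	87130
chr1	87742	88037
chr1	88358	88525
chr1	88665	90290
chr1	91855	92477
chr1	96332	96511
chr1	99751	99982
chr1	100046	100918
chr1	103118	104167
chr1	105783	106393
chr1	108148	108339
chr1	109982	110835
chr1	111972	112153
chr1	112924	113377
chr1	115722	117230
chr1	119986	120598
chr1	120976	123801
chr1	124154	124716
chr1	126343	127472
chr1	129432	130288
chr1	132598	132959
chr1	134262	135161
chr1	139513	139935
chr1	141032	141274
chr1	141898	142198
chr1	143013	143725
chr1	145036	146487
chr1	152082	152378
chr1	155646	156238
chr1	156369	158059
chr1	158156	158978
chr1	159097	159487
chr1	160307	161292
chr1	162159	162781
chr1	164213	164896
chr1	167145	168549
chr1	169815	170647
chr1	171130	171341
chr1	172340	173437
chr1	173666	174298
chr1	174406	175871
chr1	175921	176548
chr1	176554	177002
chr1	180382	180990
chr1	181641	182181
chr1	183718	184207
chr1	184874	185174
chr1	185796	186199
chr1	191070	191763
chr1	193833	194160
chr1	194231	194471
chr1	195726	196286
chr1	198190	198824
chr1	199470	199881
chr2	316	745
chr2	1925	2876
chr2	3372	4053
chr2	6738	7633
chr2	15401	16085
chr2	17564	18354
chr2	19495	20286
chr2	21026	21941
chr2	23535	24381
chr2	33973	35245
chr2	35221	35566
chr2	36385	37855
chr2	39896	40773
chr2	41512	41770
chr2	43747	44550
chr2	45111	45520
chr2	50489	51245
chr2	52507	52903
chr2	55019	55497
chr2	57586	58012
chr2	58048	58887
chr2	59449	59763
chr2	62494	63490
chr2	63834	65423
chr2	69518	70241
chr2	70661	71195
chr2	71508	71709
chr2	74065	75236
chr2	76362	77197
chr2	77453	78005
chr2	78067	78309
chr2	81602	82013
chr2	82779	82988
chr2	83649	84357
chr2	87860	88610
chr2	90448	90672
chr2	92797	93308
chr2	96166	97571
chr2	90303	90712
chr2	6482	6839
chr2	33248	33854
chr1	63157	63692
chr1	191451	191845
chr1	34208	34482
chr1	152058	152258
chr2	85698	85880
chr2	76717	77184
chr1	195081	195301
chr1	104180	104415
chr1	142812	143102
chr1	155902	156355
chr1	86883	87202
chr1	96054	96590
chr1	39449	40071
chr1	84329	84655
chr1	127352	127960
chr2	19842	20524
chr1	52028	52728
chr1	140189	140828
chr1	25683	26120
chr1	56500	56822
chr1	175847	176356
chr2	62873	63375
chr2	37416	37723
chr2	50406	50889
chr1	85973	86533
chr2	64602	65285
chr1	12096	12641
chr1	15322	15754
chr1	17804	18305
chr2	17453	17628
chr2	90608	90980
chr2	39668	39907
chr1	150425	151051
chr2	81040	81442
chr1	127654	127929
chr2	64052	64586
chr1	111336	111768
chr1	100228	100414
chr1	90878	91323
chr1	121978	122308
chr2	97407	97982
chr1	143573	144160
chr1	86829	87325
chr2	83195	83520
chr1	129392	129722
chr1	170927	171107
chr1	35040	35383
chr1	94746	95074
chr2	51693	51883
chr2	34092	34331
chr1	5657	6316
chr1	166757	167382
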