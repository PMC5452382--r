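chr1	5050	5693
chr1	8400	8774
chr1	9403	10136
chr1	15901	16758
chr1	17304	18748
chr1	20047	20903
chr1	23375	23825
chr1	26179	26355
chr1	29038	29343
chr1	32000	33676
chr1	37494	38362
chr1	38966	39762
chr1	40035	40315
chr1	40332	41249
chr1	45755	47050
chr1	52927	53700
chr1	58121	58583
chr1	59161	59347
chr1	70704	72144
chr1	73049	73481
chr1	76188	76475
chr1	81814	82459
chr1	82849	83547
chr1	83691	84582
chr1	85482	87183
chr1	88410	88577
chr1	100083	100955
chr1	103060	104109
chr1	105721	106331
chr1	108135	108326
chr1	109980	110833
chr1	112918	113371
chr1	115662	117170
chr1	120009	120621
chr1	125498	126085
chr1	128467	128824
chr1	129449	130305
chr1	131100	131342
chr1	132630	132991
chr1	134290	135189
chr1	138542	139439
chr1	139531	139953
chr1	141072	141314
chr1	141880	142180
chr1	142673	142893
chr1	152143	152439
chr1	156345	158035
chr1	158138	158960
chr1	159124	159514
chr1	160350	161335
chr1	164168	164851
chr1	165804	166795
chr1	172349	173446
chr1	173650	174282
chr1	176591	177039
chr1	180434	181042
chr1	183712	184201
chr1	184904	185204
chr1	185769	186172
chr1	186437	188175
chr1	190668	190829
chr1	193858	194185
chr1	194264	194504
chr1	195734	196294
chr1	198174	198808
chr1	199525	199936
chr2	327	756
chr2	1952	2903
chr2	3379	4060
chr2	6752	7647
chr2	9361	10125
chr2	12220	12559
chr2	16604	17367
chr2	17627	18417
chr2	20979	21894
chr2	23489	24335
chr2	30191	31451
chr2	41503	41761
chr2	43399	43721
chr2	45063	45472
chr2	50550	51306
chr2	52507	52903
chr2	55022	55500
chr2	57585	58011
chr2	60124	61334
chr2	63856	65445
chr2	69560	70283
chr2	71548	71749
chr2	72080	72273
chr2	74098	75269
chr2	76304	77139
chr2	78049	78291
chr2	81562	81973
chr2	82782	82991
chr2	83716	84424
chr2	86471	87300
chr2	87937	88687
chr2	89009	89888
chr2	90480	90704
chr2	93538	94155
chr2	96125	97530
chr2	98093	99672
chr1	160256	160682
chr2	13856	14362
chr1	126896	127485
chr1	134531	135026
chr1	123507	123880
chr1	152401	153084
chr2	63287	63624
chr1	26962	27436
chr1	117110	117710
chr1	146504	146830
chr1	12581	12742
chr1	183282	183522
chr1	86133	86384
chr1	102737	103223
chr2	98659	99117
chr1	181997	182328
chr2	37237	37574
chr1	130796	131129
chr2	56424	57110
chr1	187846	188539
chr2	33220	33565
chr1	20253	20915
chr1	104485	105132
chr2	828	1434
chr1	151824	151992
chr2	984	1213
chr2	52381	52548
chr1	96623	97300
chr1	198783	199235
chr2	25108	25624
chr1	105674	106203
chr2	93877	94225
chr2	73929	74133
chr1	101485	101751
chr2	60605	61109
chr1	91832	92495
chr2	11514	12198
chr1	161710	161914
chr1	106349	106990
chr1	140179	140468
chr2	26842	27163
chr1	22564	23162
chr1	175120	175530
chr2	681	1374
chr1	139657	140113
chr1	172743	172938
chr1	60325	60596
chr2	32026	32299
chr1	170971	171301
chr1	56975	57233
chr1	166498	166692
chr1	131188	131349
chr2	17989	18139
chr1	195541	196044
chr1	160116	160579
chr2	3111	3483
chr1	56327	56551
chr1	75762	76055
chr1	107580	108183
chr1	116054	116281
chr2	35203	35505
chr1	72856	73035
chr1	159000	159633
chr1	148185	148649
chr1	73067	73371
chr1	71776	72129
chr1	53081	53421
chr1	75445	75761
chr1	108080	108316
chr1	187129	187510
chr2	5145	5758
chr2	93719	94192
chr1	174628	174781
chr2	5250	5768
chr1	186398	186873
chr1	136931	137490
chr2	22522	22896
chr2	93172	93794
chr1	11926	12235
chr1	4896	5253
chr2	81990	82590
chr2	23519	23782
chr2	51751	52063
chr2	17405	17691
chr1	137793	138244
chr2	63033	63396
chr1	178102	178440
chr1	65298	65523
chr1	50786	51421
chr1	147194	147409
chr2	17773	18203
chr2	20496	20800
chr1	35031	35540
chr1	143064	143513
chr2	70542	71038
chr1	180919	181400
chr1	142617	143174
chr2	32098	32280
chr1	49627	50144
chr1	62612	63170
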