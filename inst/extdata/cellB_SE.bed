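chr1	5120	5763
chr1	6043	6348
chr1	6822	7018
chr1	11118	11944
chr1	17299	18743
chr1	24516	25384
chr1	32019	33695
chr1	40258	40538
chr1	40374	41291
chr1	42967	43453
chr1	48946	49741
chr1	58092	58554
chr1	62505	62781
chr1	63900	64325
chr1	68057	68653
chr1	72930	73362
chr1	76043	76330
chr1	83507	84398
chr1	87966	88261
chr1	88449	88616
chr1	88483	90108
chr1	92136	92758
chr1	96480	96659
chr1	99589	99820
chr1	100054	100926
chr1	103032	104081
chr1	108159	108350
chr1	113836	114452
chr1	115666	117174
chr1	119878	120490
chr1	121120	123945
chr1	123943	124505
chr1	126437	127566
chr1	129546	130402
chr1	131259	131501
chr1	132443	132804
chr1	134198	135097
chr1	138447	139344
chr1	139304	139726
chr1	140802	141044
chr1	142054	142354
chr1	142710	142930
chr1	143152	143864
chr1	155759	156351
chr1	160077	161062
chr1	162365	162987
chr1	163880	164031
chr1	167031	168435
chr1	181772	182312
chr1	186666	188404
chr1	190883	191044
chr1	192599	193951
chr1	193728	194055
chr1	199301	199712
chr2	260	689
chr2	1724	2675
chr2	8012	8478
chr2	9582	10346
chr2	16442	17205
chr2	19512	20303
chr2	30080	31340
chr2	35784	36360
chr2	39994	40871
chr2	43258	43580
chr2	43695	44498
chr2	45029	45438
chr2	52760	53156
chr2	54960	55438
chr2	59269	59583
chr2	62409	63405
chr2	71305	71506
chr2	72022	72215
chr2	73939	75110
chr2	77336	77888
chr2	78174	78416
chr2	81787	82198
chr2	82819	83028
chr2	83441	84149
chr2	91617	92335
chr2	92908	93419
chr2	93299	93916
chr2	94534	95039
chr2	96207	97612
chr1	28181	28677
chr1	45713	46275
chr2	71794	72430
chr2	62696	63164
chr1	27780	28047
chr1	35460	35645
chr1	189679	190114
chr1	89397	89744
chr1	177784	178084
chr1	11967	12289
chr1	49850	50375
chr1	171672	172007
chr1	119580	119876
chr1	114097	114736
chr1	20162	20843
chr1	89304	89613
chr2	41860	42385
chr1	72691	73068
chr1	128696	129023
chr1	189565	190036
chr1	98684	99048
chr2	84774	85253
chr1	194361	194807
chr1	12194	12367
chr1	39257	39601
chr2	17525	18012
chr1	153572	154200
chr1	158107	158510
chr1	78131	78663
chr1	112886	113457
chr1	9233	9858
chr2	33988	34205
chr1	34754	34985
chr1	66093	66348
chr1	57692	58361
chr1	96370	96758
chr1	188270	188555
chr1	86572	87082
chr1	14479	14712
chr2	22751	23099
chr2	42854	43429
chr1	86113	86641
chr2	454	1091
chr2	3557	4027
chr1	41826	42422
chr1	149873	150255
chr1	21538	21719
chr1	166599	166867
chr1	92810	93479
chr1	44151	44826
chr1	55341	55912
chr1	121171	121684
chr1	191927	192201
chr1	168040	168701
chr2	13707	13917
chr1	83878	84350
chr2	21523	22035
chr1	56224	56612
chr1	161872	162312
chr2	31207	31647
chr1	94413	94991
chr2	77216	77775
chr2	40177	40472
chr1	34710	35200
chr1	76452	76764
chr2	23529	23769
chr2	20465	20688
chr2	53656	54034
chr2	95720	96111
chr1	66133	66498
chr1	147779	148390
chr2	89025	89377
chr1	197412	197809
chr1	115287	115835
chr2	49287	49469
chr1	30197	30650
chr1	106164	106772
chr1	152561	153026
chr1	20911	21272
chr1	116904	117059
chr1	107137	107508
chr2	73751	74425
chr2	7987	8547
chr1	126199	126441
chr2	61899	62088
chr1	29755	30396
chr2	75619	75859
chr2	10902	11280
chr1	138762	139379
chr2	23087	23611
chr2	56881	57356
chr2	92236	92875
chr2	97908	98343
chr1	131445	131685
chr1	188040	188724
chr1	33325	33638
chr1	137579	138162
chr2	12789	12979
chr2	53618	54250
chr1	86118	86600
chr2	60465	60722
chr2	75245	75862
chr2	22423	22752
chr1	67464	67945
chr2	14001	14508
chr1	52490	53114
chr2	85674	86368
chr2	53089	53473
chr2	90842	91330
chr2	9454	9979
chr1	13231	13831
chr1	72	522
chr1	169320	169931
chr1	33660	34086
chr2	17915	18298
chr1	152425	152844
chr1	43072	43257
chr1	195698	196054
chr2	40247	40689
chr1	65463	65722
chr1	40832	41041
chr1	39468	40160
chr1	125458	125795
chr1	97156	97542
chr1	45589	46012
chr1	39247	39499
chr1	138959	139317
chr1	17194	17356
chr1	195563	196221
chr2	45045	45655
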