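chr1	5082	5725
chr1	5881	6186
chr1	6657	6853
chr1	8465	8839
chr1	9392	10125
chr1	17290	18734
chr1	19976	20832
chr1	21518	22134
chr1	23396	23846
chr1	24178	24384
chr1	24701	25569
chr1	26157	26333
chr1	31946	33622
chr1	37541	38409
chr1	38977	39773
chr1	39955	40235
chr1	40316	41233
chr1	43021	43507
chr1	56395	56914
chr1	59154	59340
chr1	60327	61638
chr1	62629	62905
chr1	63876	64301
chr1	68142	68738
chr1	70767	72207
chr1	73059	73491
chr1	76195	76482
chr1	82941	83639
chr1	83712	84603
chr1	87676	87971
chr1	88672	90297
chr1	91924	92546
chr1	96258	96437
chr1	100072	100944
chr1	103115	104164
chr1	108099	108290
chr1	110015	110868
chr1	111976	112157
chr1	112931	113384
chr1	115765	117273
chr1	120901	123726
chr1	124105	124667
chr1	126355	127484
chr1	128373	128730
chr1	129405	130261
chr1	131096	131338
chr1	132532	132893
chr1	134283	135182
chr1	138563	139460
chr1	141050	141292
chr1	143053	143765
chr1	144992	146443
chr1	152157	152453
chr1	155681	156273
chr1	156324	158014
chr1	160337	161322
chr1	162200	162822
chr1	164018	164169
chr1	164156	164839
chr1	165765	166756
chr1	167096	168500
chr1	169812	170644
chr1	173657	174289
chr1	176552	177000
chr1	180420	181028
chr1	183784	184273
chr1	185774	186177
chr1	186518	188256
chr1	190684	190845
chr1	191079	191772
chr1	193875	194202
chr1	194192	194432
chr1	195680	196240
chr1	199466	199877
chr2	346	775
chr2	1953	2904
chr2	6668	7563
chr2	8084	8550
chr2	15383	16067
chr2	16577	17340
chr2	17593	18383
chr2	21056	21971
chr2	23551	24397
chr2	27977	28539
chr2	30123	31383
chr2	35237	35582
chr2	35585	36161
chr2	39889	40766
chr2	43783	44586
chr2	54950	55428
chr2	57627	58053
chr2	58067	58906
chr2	60145	61355
chr2	69509	70232
chr2	74063	75234
chr2	76421	77256
chr2	77527	78079
chr2	78056	78298
chr2	81544	81955
chr2	86561	87390
chr2	87857	88607
chr2	89064	89943
chr2	90455	90679
chr2	94535	95040
chr2	98118	99697
chr2	69022	69513
chr1	96189	96371
chr1	10824	11118
chr1	159359	160028
chr2	81216	81600
chr1	29881	30331
chr2	92717	93329
chr2	19268	19540
chr2	73958	74346
chr1	104267	104572
chr1	150494	150895
chr2	97626	97870
chr2	80102	80646
chr1	165959	166459
chr1	128048	128277
chr1	145491	146046
chr2	62692	62920
chr1	68666	69289
chr1	150098	150528
chr1	45347	45943
chr1	21521	21905
chr2	49798	50248
chr1	68659	69043
chr2	8815	8977
chr2	15477	16122
chr2	70977	71500
chr1	62682	62838
chr1	163833	164200
chr1	181403	181834
chr1	120035	120624
chr1	32660	33318
chr1	108411	108718
chr2	91075	91709
chr1	65949	66630
chr1	57467	57781
chr2	11086	11738
chr1	112175	112530
chr1	63899	64097
chr2	75558	76129
chr1	155749	155953
chr1	59816	60239
chr1	41959	42336
chr1	15101	15322
chr1	175555	175775
chr1	131634	131966
chr1	62322	62699
chr1	95779	96312
chr2	32299	32602
chr1	161299	161777
chr1	171247	171500
chr1	127767	128123
chr1	67909	68385
chr1	53609	54100
chr1	43568	43795
chr1	71859	72306
chr1	172854	173374
chr1	97951	98483
chr1	4322	5010
chr1	152149	152646
chr2	1965	2193
chr1	140787	141204
chr1	156386	156635
chr1	47833	48051
chr1	40117	40283
chr1	140090	140562
chr1	148244	148439
chr2	49741	50256
chr1	18903	19563
chr1	116916	117251
chr1	180124	180621
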