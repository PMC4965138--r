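# Amplicon target regions (hg19), 1-based closed coordinates.
# Columns: name, chrom, start, end, strand, probe annotation.
BSP_1	chr1	156627114	156627680	+	cg22168255
BSP_2	chr1	169555680	169556264	+	cg16054275
BSP_3	chr2	236401705	236402272	+	cg04856858
BSP_4	chr4	56685682	56686292	+	cg16606320
BSP_5	chr4	123842961	123843567	+	cg11169569
BSP_6	chr5	92956435	92957014	+	cg07803236
BSP_7	chr5	102898348	102898928	+	cg07655627
BSP_8	chr5	140811383	140811992	+	cg07489502
BSP_9	chr6	31627378	31627976	+	cg15415945
BSP_10	chr6	31782716	31783294	+	cg01639032
BSP_11	chr6	69344106	69344700	+	cg14031178
BSP_12	chr6	166578845	166579411	+	cg20114732
BSP_13	chr7	5013232	5013795	+	cg20160885
BSP_14	chr7	8476807	8477405	+	cg06981279
BSP_15	chr9	139939384	139939993	+	cg10664754
BSP_16	chr10	6620279	6620895	+	cg01389728
BSP_17	chr10	50886735	50887303	+	cg05378118
BSP_18	chr10	135054458	135055053	+	cg13493048
BSP_19	chr11	66206007	66206593	+	cg10495424
BSP_20	chr12	56521723	56522328	+	cg12620342
BSP_21	chr13	78271193	78271766	+	cg07847733
BSP_22	chr13	95952581	95953201	+	cg26685941
BSP_23	chr17	17400283	17400878	+	cg22981296
BSP_24	chr17	26699283	26699850	+	cg23887396
BSP_25	chr17	77136522	77137125	+	cg17042243
BSP_26	chr17	80372192	80372799	+	cg07929164
BSP_27	chr18	74820183	74820764	+	cg16762684
BSP_28	chr19	13213177	13213768	+	cg15013019
BSP_29	chr19	18319085	18319669	+	cg15234155
BSP_30	chr19	52390719	52391331	+	cg10635122
BSP_31	chr19	55863991	55864613	+	cg26562532
BSP_32	chr19	58038315	58038921	+	cg10729426
BSP_33	chr19	58514467	58515036	+	cg12259537
BSP_34	chr20	36156592	36157203	+	cg19650416
BSP_35	chr21	46360144	46360741	+	cg23285465
BSP_36	chrX	69509900	69510480	+	cg16256230
BSP_37	chr14	64854967	64855580	+	cg00691969
BSP_38	chr10	436294	436908	+	cg01361261
BSP_39	chr11	43755257	43755859	+	cg02468154
BSP_40	chr16	15188232	15188848	+	cg03152385
BSP_41	chr6	15538245	15538860	+	cg04611912
BSP_42	chr3	55515356	55515967	+	cg05781968
BSP_43	chr11	1469829	1470436	+	cg07479615
BSP_44	chr19	35617292	35617893	+	cg08480266
BSP_45	chr5	180288564	180289135	+	cg11635304
BSP_46	chr5	139682567	139683184	+	cg11924368
BSP_47	chr10	27703028	27703636	+	cg15283904
BSP_48	chr7	4797688	4798279	+	cg17466748
BSP_49	chr8	145531650	145532255	+	cg22989161
BSP_50	chr11	47236289	47236904	+	cg26408937
BSP_51	chr6	138893354	138893947	+	cg00224202
BSP_52	chr6	33048458	33049047	+	cg12893780
BSP_53	chr11	111169587	111170180	+	cg15081566
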