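protein	description	R18_A	R18_B	R18_C	R18_D	R18_E	R22_A	R22_B	R22_C	R22_D	R22_E
P0001	synthetic protein 1	786831.7	1233275.1	1381285.9	1532239	880403.8	1530738.4	991494.6	935318	1142396	915604.5
P0002	synthetic protein 2	22230.5	33891.8	40511.9	39925.8	33325.8	4630928.3	5168909.5	5150246.2	6467965.2	4499764.9
P0003	synthetic protein 3	317773.7	289436.9	360648.9	457732.4	279414.4	369993.6	271942.6	219448	274224.7	326135.8
P0004	synthetic protein 4	1824914.2	2066002.7	1549017	1971123.3	NA	2319695.9	2441665.5	1818269.7	NA	2729434.8
P0005	synthetic protein 5	25384.8	25703.8	18332	24650.4	23794.8	29899.2	21127	42261.8	34468.7	28969.7
P0006	synthetic protein 6	121786.5	71225.5	154534.1	119793.1	77243.3	113631.8	110320.4	95847.6	97070	129493.7
P0007	synthetic protein 7	139927.8	NA	61088.5	65538.4	85775.4	69705.9	69102.6	NA	59399	97179.5
P0008	synthetic protein 8	2391415	2573633.9	3031931.3	1574417.1	2352432.8	3212802.4	2182760.6	3158641.3	1668295	1967938
P0009	synthetic protein 9	1529259.7	2509646.3	3219306	3600951.2	1991539.9	2084701.3	3729884.5	NA	2973771.9	3118993.1
P0010	synthetic protein 10	76355.7	124725	113097.5	111347.6	85348.8	106130.3	94714.9	97783.3	93593.4	73063.3
P0011	synthetic protein 11	622918.7	932484.8	679420.5	836972.6	1054241.4	750531.7	884045.7	NA	961209.5	812214.4
P0012	synthetic protein 12	1724294.5	1572980.9	1708136.1	1647403.4	NA	125203.2	146108.5	152088	145645.8	207957.4
P0013	synthetic protein 13	57049.2	52880.8	34176.7	59886.7	59623.2	52005.6	33886.2	54172.4	37268.5	70199.7
P0014	synthetic protein 14	181287.3	230862.4	147008.7	154130.5	100588.5	144450.4	175752.6	142848.7	181109	159292.8
P0015	synthetic protein 15	2123467	2209037.2	1663184.8	1664842.6	1174259.7	117414.7	79632	154490.7	104095.2	133293.3
P0016	synthetic protein 16	93067.6	63583.3	82367.4	64980.8	71616.8	48013.1	65014	52394.7	94047.6	63082
P0017	synthetic protein 17	49564.1	39452.9	40545.1	30606	49912	34662.8	40470.3	59195.2	75676	53914.2
P0018	synthetic protein 18	226191.5	114609.8	NA	163768	241339	171264.8	172512.4	162891	177273.3	NA
P0019	synthetic protein 19	23195.5	20115.1	28851.5	20206.9	33758.5	30424.9	23134.2	38777.5	22364.4	NA
P0020	synthetic protein 20	2132678.4	3892111.1	1762362	1277919.5	3931675	3741160.8	8778445.1	5307290.6	6632016.9	7513207.1
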