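population	location	region	region_name	lat	lon	alt_m	n	hd	pi_e3	haplotypes
SY	Kunyu Mt, Yantai, Shandong	1	Northeastern China and Korean Peninsula	37.3	121.75	223	10	0.000	0.00	H11:10
LD	Dahei Mt, Dalian, Liaoning	1	Northeastern China and Korean Peninsula	39.1	121.8	180	10	0.000	0.00	H8:10
LZ	Zhuanghe, Dalian, Liaoning	1	Northeastern China and Korean Peninsula	39.983333	122.966667	250	17	0.000	0.00	H6:17
CN	Baekwoon Mt, Cheonnam, Korea	1	Northeastern China and Korean Peninsula	35.066667	127.6	482	9	0.500	0.63	H6:6;H7:3
KC	Wolak Mt, Chungbuk, Korea	1	Northeastern China and Korean Peninsula	36.85	128.066667	335	12	0.000	0.00	H7:12
KK	Yangyang, Kangwon, Korea	1	Northeastern China and Korean Peninsula	37.933333	128.7	487	9	0.222	0.28	H5:8;H20:1
HX	Baian, Xingtai, Hebei	2	Northern China	37.083333	113.833333	801	12	0.167	0.00	H5:1;H15:11
TL	Tuoliang Scenic Area, Shijiazhuang, Hebei	2	Northern China	38.683333	113.816667	1145	10	0.000	0.00	H3:10
HYS	Hongya Mt, Baoding, Hebei	2	Northern China	39.483333	115.483333	516	12	0.000	0.00	H15:12
PG	Sizuolou Forest, Pinggu, Beijing	2	Northern China	40.25	117.116667	260	16	0.400	1.02	H3:4;H24:12
AK	Xiangxidong, Ankang, Shaanxi	3	Northwestern China	32.666667	109.033333	370	12	0.409	0.52	H2:3;H3:9
TGB	Tuguanpu, Hanzhong, Shaanxi	3	Northwestern China	33.1	106.7	715	4	0.000	0.00	H12:4
NY	Baotianman, Nanyang, Henan	3	Northwestern China	33.5	111.916667	1112	13	0.154	0.10	H5:1;H23:12
LGT	Louguantai National Forest Park, Xi'an, Shaanxi	3	Northwestern China	34.05	108.266667	701	8	0.000	0.00	H11:8
TB	Taibai Mt, Baoji, Shaanxi	3	Northwestern China	34.083333	107.7	2007	10	0.000	0.00	H2:10
SMX	Ganshan Mt, Sanmenxia, Henan	3	Northwestern China	34.5	111.216667	1121	6	0.000	0.00	H3:6
BMT	Baimatan, Yan'an, Shaanxi	3	Northwestern China	35.533333	110.266667	960	7	0.000	0.00	H5:7
GT	Dongcha Forest, Tianshui, Gansu	3	Northwestern China	35.533333	110.116667	1028	13	0.154	0.10	H2:12;H5:1
JX	Yunshan Reclamation Field, Yongxiu, Jiangxi	4	Central-Eastern China	29.083333	115.616667	360	13	0.500	0.88	H2:9;H11:3;H19:1
CW	Chawan Forest, Huangshan, Anhui	4	Central-Eastern China	29.6	117.55	459	8	0.000	0.00	H8:8
HZ	West Tianmu Mt, Hangzhou, Zhejiang	4	Central-Eastern China	30.2	120.0	349	10	0.533	0.23	H4:1;H5:7;H10:1;H18:1
HY	Yichang, Hubei	4	Central-Eastern China	30.433333	111.2	276	11	0.764	0.69	H2:5;H3:1;H12:3;H16:1;H17:1
BMH	Baimiaohe, Luotian, Hubei	4	Central-Eastern China	31.016667	115.766667	312	14	0.143	0.18	H3:13;H4:1
MS	Maoshan Forest, Huoshan, Anhui	4	Central-Eastern China	31.35	116.083333	659	12	0.318	0.38	H14:1;H21:1;H22:10
FJY	Fangjiaya, Nanzhang, Hubei	4	Central-Eastern China	31.75	111.933333	237	13	0.154	0.00	H12:12;H13:1
XY	Nanwan Scenic Area, Xinyang, Henan	4	Central-Eastern China	32.116667	114.0	131	8	0.821	1.11	H3:2;H15:2;H25:1;H26:3
NJ	Xiashu Forest, Jurong, Jiangsu	4	Central-Eastern China	32.133333	119.2	160	10	0.000	0.00	H8:10
AF	Fengyang, Anhui	4	Central-Eastern China	32.65	117.566667	28	12	0.000	0.00	H1:12
AX	Huangzangyu National Park, Xiaoxian, Anhui	4	Central-Eastern China	34.016667	117.05	117	11	0.000	0.00	H1:11
DX	Dangxi, Nanping, Fujian	5	Southeastern China	28.033333	118.683333	704	7	0.000	0.00	H5:7
FD	Dehua, Quanzhou, Fujian	5	Southeastern China	25.75	118.316667	484	12	0.000	0.00	H11:12
GD	Nanling National Forest Park, Guangdong	5	Southeastern China	24.916667	113.083333	500	3	0.000	0.00	H11:3
GX	Pinglou, Tianlin, Guangxi	6	Southwestern China	24.433333	105.933333	696	11	0.000	0.00	H5:11
YA	Wenquan Town, Anning, Yunnan	6	Southwestern China	24.983333	102.45	1826	15	0.000	0.00	H5:15
YB	Baoshan Mt, Baoshan, Yunnan	6	Southwestern China	25.116667	99.466667	1821	12	0.530	0.31	H4:3;H5:8;H21:1
YL	Shigu Town, Lijiang, Yunnan	6	Southwestern China	26.866667	99.666667	112	8	0.000	0.00	H2:8
HH	Kang Long Nature Reserve, Huaihua, Hunan	6	Southwestern China	27.516667	110.1	455	14	0.143	0.09	H5:1;H14:13
DM	Damao Island, Zhoushan, Zhejiang	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	29.966667	122.05	92	11	0.327	0.42	H9:9;H10:2
ZP	Panzhi, Zhoushan, Zhejiang	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	29.983333	122.066667	84	12	0.000	0.00	H9:12
ZY	Yancang, Zhoushan, Zhejiang	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	30.033333	122.083333	42	12	0.000	0.00	H9:12
TN	Shou-Cheng Mt, Nantou, Taiwan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	24.083333	121.033333	756	6	0.333	0.42	H5:1;H11:5
TK	Guguan, Taichung, Taiwan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	24.2	121.0	750	9	0.000	0.00	H11:9
TT	Wuling Farm, Taoshan, Taiwan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	24.4	121.3	1910	11	0.000	0.00	H11:11
TH	Kengzihkou Range, Hsinchu, Taiwan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	24.883333	120.966667	100	14	0.000	0.00	H11:14
JY	Gabizan Mt, Yamaguchi, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	33.933333	131.966667	99	7	0.000	0.00	H11:7
JT	Okayama, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	34.716667	133.9	200	11	0.000	0.00	H11:11
JH	Kamagamine Mt, Hiroshima, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	34.933333	132.933333	511	12	0.000	0.00	H11:12
JK	Experimental Plot of Lake Biwa, Kyoto, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	35.183333	135.9	193	12	0.000	0.00	H11:12
JG	Matsuno Lake, Gifu, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	35.416667	137.183333	208	8	0.000	0.00	H11:8
JN	Iida, Nagano, Japan	7	Zhoushan and Japanese Archipelagoes and Taiwan Island	35.583333	137.933333	473	9	0.000	0.00	H11:9
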