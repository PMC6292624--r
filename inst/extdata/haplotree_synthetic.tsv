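name	parent	level	variants
mt-MRCA	-	root	
L0	mt-MRCA	macro	101:G,138:G,175:G
L1	mt-MRCA	macro	212:G,249:G,286:G
L2	mt-MRCA	macro	323:G,360:G,397:G
L3	mt-MRCA	macro	434:G,471:G,508:G
L4	mt-MRCA	macro	545:G,582:G,619:G
L5	mt-MRCA	macro	656:G,693:G,730:G
L6	mt-MRCA	macro	767:G,804:G,841:G
M	mt-MRCA	macro	878:G,915:G,952:G
N	mt-MRCA	macro	989:G,1026:G,1063:G
R	mt-MRCA	macro	1100:G,1137:G,1174:G
C	M	hg	1211:G,1248:G,1285:G
D4	M	hg	1322:G,1359:G,1396:G
G	M	hg	1433:G,1470:G,1507:G
M1	M	hg	1544:G,1581:G,1618:G
Z	M	hg	1655:G,1692:G,1729:G
A	N	hg	1766:G,1803:G,1840:G
I	N	hg	1877:G,1914:G,1951:G
W	N	hg	1988:G,2025:G,2062:G
X	N	hg	2099:G,2136:G,2173:G
Y	N	hg	2210:G,2247:G,2284:G
H	R	hg	2321:G,2358:G,2395:G
V	R	hg	2432:G,2469:G,2506:G
U	R	hg	2543:G,2580:G,2617:G
K	R	hg	2654:G,2691:G,2728:G
T	R	hg	2765:G,2802:G,2839:G
J	R	hg	2876:G,2913:G,2950:G
F	R	hg	2987:G,3024:G,3061:G
B	R	hg	3098:G,3135:G,3172:G
H1	H	subhg	3209:G,3246:G,3283:G
H2	H	subhg	3320:G,3357:G,3394:G
H3	H	subhg	3431:G,3468:G,3505:G
H4	H	subhg	3542:G,3579:G,3616:G
H5	H	subhg	3653:G,3690:G,3727:G
U1	U	subhg	3764:G,3801:G,3838:G
U2	U	subhg	3875:G,3912:G,3949:G
U4	U	subhg	3986:G,4023:G,4060:G
U5a	U	subhg	4097:G,4134:G,4171:G
U5b	U	subhg	4208:G,4245:G,4282:G
U6	U	subhg	4319:G,4356:G,4393:G
U7	U	subhg	4430:G,4467:G,4504:G
U8	U	subhg	4541:G,4578:G,4615:G
K1	K	subhg	4652:G,4689:G,4726:G
K2	K	subhg	4763:G,4800:G,4837:G
J1	J	subhg	4874:G,4911:G,4948:G
J2	J	subhg	4985:G,5022:G,5059:G
T1	T	subhg	5096:G,5133:G,5170:G
T2	T	subhg	5207:G,5244:G,5281:G
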