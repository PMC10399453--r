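subject_id,V001,V002,V003,V004,V005,V006,V007,V008,y
1,-0.963945990797619,2,1.80797205450957,1,1.70903721899955,2,-0.595135487681689,1,
2,0.307252246310505,3,0.905450175531196,1,-0.338286336177566,2,-3.18338415517961,2,
3,1.14063333191887,2,2.4291481553828,2,-1.98127390573566,3,-4.89676149609765,4,3.79744086341739
4,-2.88802786117706,1,0.0645454725904523,4,3.08226549139944,2,2.30547795362331,1,
5,-1.6023402496798,4,-0.631985442742656,4,2.45581653318601,4,1.9773223574831,3,-18.9122914013348
6,1.03457916132262,2,-0.953968112847556,3,0.476243316360654,4,-0.361397481116415,3,-13.4586062636465
7,-3.49540433364195,1,-1.82879935692412,1,1.03455209161498,1,-1.97538584526305,1,-11.1629265092158
8,-0.718277914048033,2,2.58024522498161,2,1.58541649977767,2,-3.94954010130362,3,
9,0.324211587636818,1,3.60826616764546,1,-0.493806033627488,3,-2.61750373151317,3,2.07134887040443
10,1.20852537738062,4,4.4720421410116,1,0.16976206755931,2,-1.10685464953415,3,-4.33111199366719
11,-0.0318652381762755,2,1.64094817787154,1,0.30365945346193,1,-2.78971995666716,1,
12,0.258165556363656,2,1.5083325451249,1,-1.42391874347408,3,-1.54324511708593,3,-5.5155114753839
13,-1.29524841693276,4,-0.538773804042088,3,1.67003952997275,2,-3.36308346173213,4,-3.21497529254878
14,-0.923926317252692,4,1.42815429810233,3,1.42519911393485,3,1.64627331686071,4,
15,-1.05214602337122,3,1.1865939154469,3,1.22408389243791,1,-1.79299892624864,3,
16,0.365356229966835,1,0.403975280328997,1,-0.211208126914653,3,-2.81282862245993,1,
17,0.483785080033919,3,-0.939231761583078,3,1.87426414799334,4,0.364767054715611,1,
18,0.961498206030051,3,2.7338177670751,2,,,-0.339882006051267,4,-4.6322035712202
19,-1.5152216454733,3,0.656609794082783,3,,,-1.7448774190688,2,
20,-0.703370033701113,3,-2.14903919530338,4,,,-0.0944937671004231,4,
21,-1.74672301551164,4,-0.133784633748177,4,,,-1.77261737025076,4,-5.89900390936951
22,-0.816895925890143,2,-1.00703906368069,2,,,-3.36714919550259,4,-5.4142179433674
23,-1.17636535477699,3,0.881729930043871,2,,,-0.101480445625595,3,
24,-0.952614856210056,1,1.79931912530736,2,,,-4.6094507047824,1,2.1764757988046
25,-0.591001923490611,3,-1.05232393352965,4,,,0.732587164177676,2,
26,-0.511859635388841,4,-0.767718342849942,3,,,0.771507876388282,3,
27,-2.45804961506403,1,0.87080419717022,2,,,-3.70904847471011,1,
28,,,,3,,,-2.01538415023942,2,-6.83397055930253
29,,,,3,,,-1.25040296403917,3,-16.4591986967601
30,,,,3,,,-2.61388567630082,3,
31,,,,4,,,-1.10277921130109,4,
32,,,,3,,,-1.43006987345379,4,-9.00260643365443
33,,,,3,,,-0.659393874907987,1,-11.0415760498886
34,,,,3,,,0.772638163123727,3,
35,,,,3,,,0.415199155069564,2,-13.9051912073836
36,,,,2,,,-3.07533745126325,2,-0.0152653922715482
37,,,,4,,,-1.5687609814899,2,-5.45741018123553
38,,,,4,,,-1.13451405311209,1,-7.30813557156804
39,,,,4,,,-2.28724825689157,4,-2.23786122392637
40,,,,2,,,-2.32801399179299,3,-1.01253662497264
41,,,,2,,,-1.26963685164033,3,-7.50653355631044
42,,,,2,,,-2.78721309849761,3,
43,,,,2,,,-2.8246097418325,2,-2.44175402669115
44,,,,4,,,-2.29695928417138,3,-9.92233296639834
45,,,,1,,,-2.32223187668735,4,-6.67312210131793
46,,,,4,,,2.08391607856652,1,-11.2595843523086
47,,,,4,,,-0.920745235641129,3,-9.84042168244047
48,,,,4,,,-0.316469530605796,4,
49,,,,3,,,1.46333349628794,2,
50,,,,3,,,-1.55365303225275,4,
51,,,,1,,,-2.92023927228019,2,3.17460413374198
52,,,,1,,,-2.10984693317962,2,
53,,,,4,,,-1.10751580130141,2,
54,,,,1,,,-1.42560726732214,1,-2.6089447700362
55,,,,1,,,-2.54874809244979,2,1.56111047895144
56,,,,2,,,-4.84853331951436,4,1.95325846396406
57,,,,2,,,-1.54893207950741,4,-4.53110295271223
58,,,,1,,,-2.19247631507014,1,0.418825651199064
59,,,,2,,,-1.51996260389233,2,2.93821098309927
60,,,,3,,,1.98437781508854,1,
61,,,,4,,,1.1822702427143,1,-11.4556561491226
62,,,,1,,,2.64917348575555,2,
63,,,,1,,,-0.768169792723366,4,
64,,,,1,,,-1.24834208219108,1,
65,,,,2,,,-3.57200066129424,2,
66,,,,4,,,-1.8164636371589,3,-5.08334179832789
67,,,,3,,,0.570604697428429,1,
68,,,,3,,,-2.61360222417145,4,-7.19097634300854
69,,,,4,,,0.26507117890179,4,
70,,,,2,,,0.604050400897014,4,
71,,,,4,,,-0.0366108920838102,1,-12.362211231578
72,,,,2,,,-5.04897149305282,3,
73,-1.38909316219245,2,2.54042153543506,1,,,-1.85723417936494,1,-2.97266149237141
74,1.43933179286341,4,1.30001396011022,3,,,2.04788944028898,3,
75,,,,4,,,-0.30959363058135,4,
76,,,,4,,,-1.13137158127082,4,
77,,,,2,,,-0.434325323797978,3,-3.88959824640809
78,,,,1,-1.19402741459311,1,-0.263038906508185,1,-2.63372495900344
79,,,,3,0.918372211359889,4,0.490794134801428,4,
80,,,,2,-0.805799643008363,3,-2.58454332981754,2,
81,,,,1,-1.82051305412642,2,-3.48688372677234,1,6.17221116119696
82,,,,3,0.0591070073836377,4,-0.471256440623084,2,
83,,,,3,-0.171368092741579,3,-2.47758534326482,4,-5.96124753697126
84,,,,2,0.761935632095515,1,-0.15242217309843,2,-6.96473892688173
85,,,,4,1.51355418324413,1,-0.0608864347113385,3,
86,,,,3,1.35822210168896,3,-0.127043456228294,3,
87,,,,1,1.22160844062961,3,-0.34664472317445,2,1.21908334729947
88,,,,4,-1.05992958131417,4,-0.98738394134849,3,-18.976442700419
89,,,,2,0.585790169816721,3,-1.36378786507596,2,
90,,,,4,1.79790855207946,4,4.34429719625915,2,
91,,,,2,2.28408448912765,1,-1.13069977962471,2,
92,,,,2,-0.179230468756877,2,-3.54351606430068,3,
93,,,,2,-0.645629255875999,4,-0.44854294499506,3,-16.73364755379
94,,,,1,0.393919845604135,3,0.61587397842247,1,
95,,,,1,-0.578810586018343,1,-1.8473783604241,4,
96,,,,2,0.937990275648001,2,-1.03533781378168,2,-5.60127141934875
97,,,,1,-0.0125524358240914,3,-4.06890383453506,4,0.329560668662942
98,,,,1,-0.370697676123464,1,-1.92134348912186,2,2.13214730448311
99,,,,3,-0.247428502142679,3,-0.394108789843136,1,
100,,,,1,0.381949427126125,1,-4.87552241103511,3,
101,,,,4,1.28921859655209,2,0.0205777259179278,4,-14.588469743494
102,,,,3,2.11858792242961,4,-1.7828794985764,4,
103,,,,4,0.117366894224995,4,-0.3980772858998,1,
104,,,,4,0.694157195548253,4,1.15374667765881,1,-12.6888574839322
105,,,,3,-0.401872587789263,2,2.17335122837465,1,
106,,,,1,0.20553247870035,4,2.31927341910667,3,
107,,,,1,-0.538884542281437,1,-4.68257328208648,1,-3.51168621998919
108,,,,3,1.14250795454185,4,-1.82845242113781,2,-3.34032459684834
109,,,,2,1.39187711836431,4,-1.28923928485175,2,-2.52036256939128
110,,,,4,1.71986514543773,1,-0.0453000714539316,2,-7.92884901058812
111,,,,4,2.51523984579018,3,1.07575167947864,1,-12.1653619036787
112,,,,4,2.56565020844847,4,-3.08122197745866,1,
113,,,,2,1.3842649175596,1,-1.19545024544174,4,
114,,,,1,1.2742903641954,1,-1.04065854482955,2,
115,,,,2,3.04114037185052,3,-1.16304656763046,2,
116,,,,3,0.807857686055205,2,0.205204820765219,4,-12.3706386270187
117,,,,3,-0.0690491571571697,2,-0.699915722985766,1,-9.73186832441899
118,,,,1,-1.53345877896312,2,-2.65095548266629,3,
119,,,,4,-0.0898205260816086,3,-2.8115975129419,4,
120,-1.4661972459151,4,2.66405029853184,2,0.907411470217367,1,-1.49278849850465,3,
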