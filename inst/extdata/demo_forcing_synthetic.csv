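"year","T","Q1","Cg"
48,14.4988369514061,1200,288
49,15.1469146593777,1200,288.004455016221
50,14.331497110072,1200,288.017820478372
51,16.2762246417102,1200,288.040097626977
52,15.2636062174523,1200,288.071288529791
53,14.3436252927056,1200,288.111396082118
54,15.3899432419428,1200,288.160424007261
55,15.5906597641034,1200,288.218376857094
56,15.4606250813228,1200,288.285260012772
57,14.7556892902749,1200,288.361079685559
58,16.2094249347607,1200,288.445842917791
59,15.3118745891291,1200,288.539557583968
60,14.5030075355666,1200,288.64223239197
61,13.228240090258,1200,288.753876884409
62,15.8999447345145,1200,288.874501440103
63,14.9640531127878,1200,289.004117275689
64,14.9870477895208,1200,289.142736447357
65,15.7550689685482,1200,289.290371852721
66,15.6569769560785,1200,289.44703723282
67,15.475121056974,1200,289.612747174248
68,15.7351818972866,1200,289.787517111417
69,15.6257090405849,1200,289.971363328956
70,15.0596519866922,1200,290.164302964237
71,13.4085186433093,1200,290.366354010038
72,15.4958605983158,1200,290.57753531734
73,14.9550970083768,1200,290.79786659826
74,14.8753635946357,1200,291.027368429112
75,13.8233980928806,1200,291.266062253619
76,14.6174799559131,1200,291.513970386242
77,15.3343532481598,1200,291.771116015663
78,16.0869436412232,1200,292.0375232084
79,14.9177698181256,1200,292.313216912559
80,15.3101372892475,1200,292.598222961726
81,14.9569559675337,1200,292.892568079007
82,13.8983523545371,1200,293.196279881199
83,14.6680043493603,1200,293.509386883109
84,14.6845680370317,1200,293.831918502019
85,14.9525492826311,1200,294.163905062289
86,15.8800202975871,1200,294.505377800108
87,15.610540598766,1200,294.856368868397
88,14.8683811229971,1200,295.216911341847
89,14.7973106558908,1200,295.587039222121
90,15.5575707003238,1200,295.966787443192
91,15.4453305589389,1200,296.356191876838
92,14.4489954443604,1200,296.755289338294
93,14.4340038744303,1200,297.164117592046
94,15.2916655697095,1200,297.582715357792
95,15.6148263396123,1200,298.011122316547
96,14.9101230302798,1200,298.449379116914
97,15.7048861811634,1200,298.897527381514
98,15.3184847042937,1200,299.355609713566
99,14.5103788853994,1200,299.823669703643
100,15.2728957531395,1200,300.301751936579
101,14.0965095231354,1200,300.789901998547
102,16.1464189613608,1200,301.288166484301
103,16.5843199188047,1200,301.796593004589
104,14.7062228188268,1200,302.315230193729
105,14.1646922989468,1200,302.844127717362
106,15.4557757019539,1200,303.383336280375
107,14.8919563168953,1200,303.932907635002
108,16.9212942084038,1200,304.492894589095
109,14.9686079978135,1200,305.063351014581
110,15.5517914899606,1200,305.644331856092
111,15.0224017270245,1200,306.235893139785
112,14.4053814328941,1200,306.838091982336
113,15.1510338396115,1200,307.450986600131
114,13.5560330968872,1200,308.074636318638
115,16.1724438892503,1200,308.70910158197
116,15.1226026705695,1200,309.354443962644
117,16.7380893362897,1200,310.010726171533
118,15.3804076231197,1200,310.678012068011
119,14.4320428552625,1200,311.356366670303
120,15.4885810827912,1200,312.045856166035
121,14.2527218946846,1200,312.746547922986
122,13.9970932798087,1200,313.458510500047
123,15.233156988414,1200,314.181813658391
124,14.6453665014253,1200,314.916528372852
125,15.0008842813053,1200,315.662726843519
126,15.0594730593213,1200,316.420482507547
127,14.5283832430495,1200,317.189870051187
128,14.5450650137452,1200,317.970965422037
129,14.8918571079009,1200,318.763845841523
130,15.9424695972586,1200,319.568589817598
131,13.7811465596562,1200,320.385277157682
132,15.4751569501027,1200,321.213988981833
133,15.2663602969708,1200,322.054807736146
134,15.8504798698211,1200,322.907817206407
135,14.7566528610926,1200,323.773102531979
136,15.296015047933,1200,324.650750219935
137,15.2136790326178,1200,325.540848159446
138,14.5659839752067,1200,326.443485636419
139,15.9662942447865,1200,327.358753348387
140,15.928322092556,1200,328.286743419668
141,15.560170919612,1200,329.227549416778
142,16.2694667636327,1200,330.181266364115
143,15.4467891404522,1200,331.147990759917
144,13.9787262332336,1200,332.127820592487
145,14.5413876686105,1200,333.120855356701
146,14.0203099080813,1200,334.127196070796
147,14.6212794908486,1200,335.146945293447
148,14.5037066582207,1200,336.18020714113
149,15.0336926985154,1200,337.227087305778
150,14.271262681158,1200,338.287693072745
151,15.1264230179233,1200,339.362133339059
152,14.4763322848649,1200,340.450518631991
153,16.4138298154981,1200,341.552961127932
154,15.5733659808138,1200,342.669574671588
155,15.7281393835962,1200,343.800474795491
156,15.3073482862611,1200,344.94577873984
157,16.3457408644155,1200,346.105605472667
158,14.4914108368408,1200,347.280075710345
159,14.6306842157115,1200,348.469311938423
160,16.1458257908333,1200,349.673438432822
161,14.4794429173517,1200,350.892581281364
162,14.8340954051184,1200,352.126868405667
163,14.6857536564464,1200,353.3764295834
164,14.7440057051612,1200,354.641396470892
165,14.7767093576188,1200,355.921902626131
166,15.3953506650143,1200,357.21808353212
167,14.8581356141843,1200,358.530076620627
168,14.5952340303086,1200,359.858021296326
169,16.0744310601363,1200,361.202058961317
170,14.8283364731625,1200,362.562333040063
171,14.8563547759653,1200,363.938989004721
172,14.9198474070292,1200,365.332174400895
173,15.5701330456411,1200,366.742038873797
174,14.9411484766989,1200,368.168734194843
175,14.9698926628264,1200,369.612414288674
176,14.4546716169955,1200,371.073235260621
177,14.7405837822029,1200,372.551355424611
178,15.0481283523476,1200,374.046935331525
179,14.5288844109923,1200,375.560137798018
180,15.4251969541061,1200,377.091127935807
181,13.7852847345706,1200,378.640073181424
182,15.2452462886318,1200,380.207143326461
183,13.7708401411699,1200,381.7925105483
184,14.7592190985307,1200,383.396349441331
185,14.577376076444,1200,385.018837048692
186,14.4783241754552,1200,386.660152894504
187,14.9544825777221,1200,388.320479016637
188,13.468512459456,1200,390
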