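index,r,g,b
0,0,0,255
1,0,4,255
2,0,8,255
3,0,12,255
4,0,16,255
5,0,20,255
6,0,24,255
7,0,28,255
8,0,32,255
9,0,36,255
10,0,40,255
11,0,44,255
12,0,48,255
13,0,52,255
14,0,56,255
15,0,60,255
16,0,64,255
17,0,68,255
18,0,72,255
19,0,76,255
20,0,80,255
21,0,84,255
22,0,88,255
23,0,92,255
24,0,96,255
25,0,100,255
26,0,104,255
27,0,108,255
28,0,112,255
29,0,116,255
30,0,120,255
31,0,124,255
32,0,128,255
33,0,132,255
34,0,136,255
35,0,140,255
36,0,144,255
37,0,148,255
38,0,152,255
39,0,156,255
40,0,160,255
41,0,164,255
42,0,168,255
43,0,172,255
44,0,176,255
45,0,180,255
46,0,184,255
47,0,188,255
48,0,192,255
49,0,196,255
50,0,200,255
51,0,204,255
52,0,208,255
53,0,212,255
54,0,216,255
55,0,220,255
56,0,224,255
57,0,228,255
58,0,232,255
59,0,236,255
60,0,240,255
61,0,244,255
62,0,248,255
63,0,252,255
64,0,255,254
65,0,255,250
66,0,255,246
67,0,255,242
68,0,255,238
69,0,255,234
70,0,255,230
71,0,255,226
72,0,255,222
73,0,255,218
74,0,255,214
75,0,255,210
76,0,255,206
77,0,255,202
78,0,255,198
79,0,255,194
80,0,255,190
81,0,255,186
82,0,255,182
83,0,255,178
84,0,255,174
85,0,255,170
86,0,255,166
87,0,255,162
88,0,255,158
89,0,255,154
90,0,255,150
91,0,255,146
92,0,255,142
93,0,255,138
94,0,255,134
95,0,255,130
96,0,255,126
97,0,255,122
98,0,255,118
99,0,255,114
100,0,255,110
101,0,255,106
102,0,255,102
103,0,255,98
104,0,255,94
105,0,255,90
106,0,255,86
107,0,255,82
108,0,255,78
109,0,255,74
110,0,255,70
111,0,255,66
112,0,255,62
113,0,255,58
114,0,255,54
115,0,255,50
116,0,255,46
117,0,255,42
118,0,255,38
119,0,255,34
120,0,255,30
121,0,255,26
122,0,255,22
123,0,255,18
124,0,255,14
125,0,255,10
126,0,255,6
127,0,255,2
128,2,255,0
129,6,255,0
130,10,255,0
131,14,255,0
132,18,255,0
133,22,255,0
134,26,255,0
135,30,255,0
136,34,255,0
137,38,255,0
138,42,255,0
139,46,255,0
140,50,255,0
141,54,255,0
142,58,255,0
143,62,255,0
144,66,255,0
145,70,255,0
146,74,255,0
147,78,255,0
148,82,255,0
149,86,255,0
150,90,255,0
151,94,255,0
152,98,255,0
153,102,255,0
154,106,255,0
155,110,255,0
156,114,255,0
157,118,255,0
158,122,255,0
159,126,255,0
160,130,255,0
161,134,255,0
162,138,255,0
163,142,255,0
164,146,255,0
165,150,255,0
166,154,255,0
167,158,255,0
168,162,255,0
169,166,255,0
170,170,255,0
171,174,255,0
172,178,255,0
173,182,255,0
174,186,255,0
175,190,255,0
176,194,255,0
177,198,255,0
178,202,255,0
179,206,255,0
180,210,255,0
181,214,255,0
182,218,255,0
183,222,255,0
184,226,255,0
185,230,255,0
186,234,255,0
187,238,255,0
188,242,255,0
189,246,255,0
190,250,255,0
191,254,255,0
192,255,252,0
193,255,248,0
194,255,244,0
195,255,240,0
196,255,236,0
197,255,232,0
198,255,228,0
199,255,224,0
200,255,220,0
201,255,216,0
202,255,212,0
203,255,208,0
204,255,204,0
205,255,200,0
206,255,196,0
207,255,192,0
208,255,188,0
209,255,184,0
210,255,180,0
211,255,176,0
212,255,172,0
213,255,168,0
214,255,164,0
215,255,160,0
216,255,156,0
217,255,152,0
218,255,148,0
219,255,144,0
220,255,140,0
221,255,136,0
222,255,132,0
223,255,128,0
224,255,124,0
225,255,120,0
226,255,116,0
227,255,112,0
228,255,108,0
229,255,104,0
230,255,100,0
231,255,96,0
232,255,92,0
233,255,88,0
234,255,84,0
235,255,80,0
236,255,76,0
237,255,72,0
238,255,68,0
239,255,64,0
240,255,60,0
241,255,56,0
242,255,52,0
243,255,48,0
244,255,44,0
245,255,40,0
246,255,36,0
247,255,32,0
248,255,28,0
249,255,24,0
250,255,20,0
251,255,16,0
252,255,12,0
253,255,8,0
254,255,4,0
255,255,0,0
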