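age_years,incidence
0,6.143166783451013e-4
1,6.70156024702232e-4
2,7.310709822408656e-4
3,7.9752290716494e-4
4,8.700150914255011e-4
5,9.490965745408736e-4
6,0.0010353663018986296
7,0.0011294776610334067
8,0.0012321434302373095
9,0.001344141176982571
10,0.0014663191470429043
11,0.0015996026889164411
12,0.0017450012622073742
13,0.0019036160830462295
14,0.0020766484644534444
15,0.002265408914814322
16,0.002471327063375132
17,0.0026959624879338527
18,0.0029410165267320667
19,0.0032083451640085923
20,0.0034999730868071686
21,0.003818109019501271
22,0.004165162452176344
23,0.0045437618895664165
24,0.004956774758758451
25,0.00540732912644096
26,0.005898837390178376
27,0.006435022123143626
28,0.007019944268051042
29,0.007658033893824235
30,0.008354123747942897
31,0.009113485858586519
32,0.009941871463791508
33,0.010845554570036048
34,0.011831379470155725
35,0.012906812580479873
36,0.014079998989791587
37,0.015359824148400343
38,0.016755981164546567
39,0.018279044217825845
40,0.019940548645649803
41,0.021753078309300164
42,0.02373036090126724
43,0.025887371915708866
44,0.028240448069478997
45,0.03080741103275109
46,0.03360770240634439
47,0.03666253096804108
48,0.03999503330310454
49,0.043630449035578694
50,0.04759631198753032
51,0.051922658714032094
52,0.056642255993282896
53,0.061790848994825044
54,0.06740743200542813
55,0.0735345437630571
56,0.08021858963571739
57,0.08751019308528712
58,0.09546457907824514
59,0.10414199234716055
60,0.11360815367076377
61,0.12393475762836002
62,0.13520001559846748
63,0.1474892481142275
64,0.16089553106195606
65,0.17552040061699692
66,0.19147462225590386
67,0.208879029669277
68,0.2278654399289899
69,0.24857765184107972
70,0.2711725350455999
71,0.2958212181120332
72,0.3227103846286335
73,0.3520436871019846
74,0.3840432893753353
75,0.41895154924763905
76,0.45703285403707794
77,0.49857562299121655
78,0.5438944917095899
79,0.593332695123052
80,0.64726466707803465
81,0.7060988762143844
82,0.7702809196150792
83,0.8402968976584314
84,0.9166770956331523
85,1
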