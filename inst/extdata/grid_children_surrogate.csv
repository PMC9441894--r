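"monthly_frequency","density"
1,0.0886070282226699
2,0.0740317616658805
3,0.061318324823007
4,0.0516821208961858
5,0.0443089602853086
6,0.0385362334954805
7,0.0339158024371383
8,0.0301463614485943
9,0.0270208250781549
10,0.02439309093286
15,0.0158291889560087
20,0.0112205576336952
25,0.00841086121034505
30,0.00655485378894936
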