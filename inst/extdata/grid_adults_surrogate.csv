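"monthly_frequency","density"
1,0.140098479470732
2,0.0931781160194222
3,0.0686659152063691
4,0.0536677501829098
5,0.0435797113220518
6,0.036357299052459
7,0.0309517546123784
8,0.02676897948721
9,0.023447146827286
10,0.0207533577528072
15,0.0125791518553382
20,0.00855877002909286
25,0.00624134402964976
30,0.00476897756880086
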