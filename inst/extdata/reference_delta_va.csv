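pupil_mm,vega2018,fernandez2019a,fernandez2019b,alarcon2016,armengol2020a,armengol2020b
1.5,0,0,0,0,0,0
2.0,0,0,0,0,0,0
2.5,0.04,0.06,0.06,0.07,0.06,0.06
3.0,0.13,0.07,0.07,0.12,0.11,0.12
3.5,0.17,0.07,0.09,0.15,0.13,0.14
4.0,0.14,0.08,0.08,0.16,0.15,0.17
4.5,0.17,0.08,0.09,0.18,0.16,0.18
5.0,0.21,0.08,0.09,0.20,0.18,0.21
5.5,0.24,0.09,0.10,0.21,0.20,0.22
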