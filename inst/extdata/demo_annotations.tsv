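annotation	retention_time_min
PC 16:0/22:6(n-3,6,9,12,15,18)	12.0
PE 16:1(n-7)_18:1(n-7)	14.0
LPC 18:1	10.0
FA 16:1	8.0
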