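wga,ltv_p3_ms,ltv_p10_ms,ltv_expected_ms,ltv_sd_ms
21,6.2,12.2,25,10
22,7.4,13.4,26.2,10
23,8.6,14.6,27.4,10
24,9.8,15.8,28.6,10
25,11,17,29.8,10
26,12.2,18.2,31,10
27,13.4,19.4,32.2,10
28,14.6,20.6,33.4,10
29,15.8,21.8,34.6,10
30,17,23,35.8,10
31,18.2,24.2,37,10
32,19.4,25.4,38.2,10
33,20.6,26.6,39.4,10
34,21.8,27.8,40.6,10
35,23,29,41.8,10
36,24.2,30.2,43,10
37,25.4,31.4,44.2,10
38,26.6,32.6,45.4,10
39,27.8,33.8,46.6,10
40,29,35,47.8,10
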