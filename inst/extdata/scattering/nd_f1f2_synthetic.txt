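# Nd 60 144.24200
2.0000 52.17089 9.274968e+00
2.1418 52.59309 8.660909e+00
2.2936 52.94238 8.087694e+00
2.4562 53.22916 7.552290e+00
2.6303 53.46166 7.052403e+00
2.8167 53.65216 6.585698e+00
3.0164 53.79118 6.149693e+00
3.2302 53.88819 5.742658e+00
3.4592 53.94340 5.362493e+00
3.7044 53.95527 5.007541e+00
3.9670 53.92363 4.676061e+00
4.2482 53.83312 4.366540e+00
4.5494 53.66525 4.077447e+00
4.8719 53.39389 3.807536e+00
5.2172 52.95552 3.555535e+00
5.5870 52.19118 3.320196e+00
5.9831 50.42196 3.100389e+00
6.4072 49.97646 7.992527e+00
6.8614 51.34519 1.048156e+01
7.3478 54.28060 1.113866e+01
7.8686 56.40835 1.002493e+01
8.4264 57.60510 9.026146e+00
9.0237 58.39956 8.130374e+00
9.6634 58.95267 7.326611e+00
10.3484 59.34507 6.605289e+00
11.0819 59.62646 5.957736e+00
11.8675 59.83346 5.376087e+00
12.7087 59.97332 4.853577e+00
13.6096 60.06813 4.383932e+00
13.8000 60.08331 4.294613e+00
14.5743 60.12900 3.961708e+00
15.6075 60.16704 3.581903e+00
16.0000 60.17470 3.453795e+00
16.7138 60.18260 3.240201e+00
17.8986 60.18362 2.932595e+00
19.1674 60.17388 2.655582e+00
20.0000 60.16403 2.497594e+00
20.5261 60.15629 2.406024e+00
21.9811 60.13312 2.181095e+00
23.5392 60.10842 1.978277e+00
25.2079 60.07875 1.795291e+00
26.9948 60.04773 1.630145e+00
28.9083 60.01618 1.481024e+00
30.9575 59.98469 1.346301e+00
33.1520 59.95478 1.224526e+00
35.5020 59.92464 1.114403e+00
38.0186 59.89565 1.014764e+00
40.7136 59.86797 9.245635e-01
43.5997 59.84171 8.428632e-01
46.6903 59.81780 7.688260e-01
50.0000 59.79446 7.016944e-01
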