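# Os 76 190.23000
2.0000 57.56311 2.059798e+00
2.1418 53.41022 1.923427e+00
2.2936 56.29200 1.365056e+01
2.4562 60.74908 1.274690e+01
2.6303 63.06244 1.190318e+01
2.8167 64.61611 1.111547e+01
3.0164 65.76662 1.037957e+01
3.2302 66.65301 9.692567e+00
3.4592 67.35792 9.050917e+00
3.7044 67.92689 8.451822e+00
3.9670 68.39729 7.892344e+00
4.2482 68.77409 7.369929e+00
4.5494 69.07999 6.881991e+00
4.8719 69.32566 6.426431e+00
5.2172 69.51853 6.001098e+00
5.5870 69.66342 5.603889e+00
5.9831 69.76806 5.232894e+00
6.4072 69.82262 4.886523e+00
6.8614 69.83017 4.563053e+00
7.3478 69.77815 4.260994e+00
7.8686 69.67774 3.978971e+00
8.4264 69.47738 3.715576e+00
9.0237 69.14252 3.469633e+00
9.6634 68.55669 3.239950e+00
10.3484 67.29055 3.025485e+00
11.0819 66.02512 7.842706e+00
11.8675 68.01476 7.104207e+00
12.7087 68.41184 9.316372e+00
13.6096 71.15739 9.898372e+00
13.8000 71.57036 9.689285e+00
14.5743 72.74729 8.911080e+00
15.6075 73.70569 8.025543e+00
16.0000 73.96290 7.727461e+00
16.7138 74.34540 7.231218e+00
17.8986 74.79527 6.518340e+00
19.1674 75.11488 5.878386e+00
20.0000 75.26664 5.514363e+00
20.5261 75.34375 5.303723e+00
21.9811 75.50608 4.787496e+00
23.5392 75.62380 4.323602e+00
25.2079 75.69844 3.906534e+00
26.9948 75.74491 3.531475e+00
28.9083 75.77008 3.194054e+00
30.9575 75.77920 2.890353e+00
33.1520 75.77844 2.616891e+00
35.5020 75.76651 2.370564e+00
38.0186 75.74819 2.148576e+00
40.7136 75.72538 1.948433e+00
43.5997 75.69955 1.767901e+00
46.6903 75.67371 1.604989e+00
50.0000 75.64489 1.457904e+00
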