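# I 53 126.90447
2.0000 47.04763 6.440173e+00
2.1418 47.18741 6.013795e+00
2.2936 47.28751 5.615777e+00
2.4562 47.34873 5.244014e+00
2.6303 47.37046 4.896911e+00
2.8167 47.35394 4.572850e+00
3.0164 47.28304 4.270105e+00
3.2302 47.14724 3.987476e+00
3.4592 46.93044 3.723504e+00
3.7044 46.58664 3.477040e+00
3.9670 46.03062 3.246873e+00
4.2482 44.93949 3.031954e+00
4.5494 38.86038 2.831219e+00
4.8719 42.49359 1.041512e+01
5.2172 45.98159 1.107391e+01
5.5870 49.08677 9.964820e+00
5.9831 50.45124 8.970273e+00
6.4072 51.32519 8.078533e+00
6.8614 51.92576 7.278505e+00
7.3478 52.35259 6.560587e+00
7.8686 52.66203 5.916234e+00
8.4264 52.87870 5.337539e+00
9.0237 53.03142 4.817744e+00
9.6634 53.13632 4.350613e+00
10.3484 53.20527 3.930722e+00
11.0819 53.24704 3.553150e+00
11.8675 53.27200 3.213427e+00
12.7087 53.27738 2.907711e+00
13.6096 53.27126 2.632432e+00
13.8000 53.26914 2.580020e+00
14.5743 53.25673 2.384491e+00
15.6075 53.23788 2.161038e+00
16.0000 53.22924 2.085567e+00
16.7138 53.21293 1.959612e+00
17.8986 53.18521 1.777923e+00
19.1674 53.15585 1.613972e+00
20.0000 53.13735 1.520307e+00
20.5261 53.12572 1.465962e+00
21.9811 53.09547 1.332276e+00
23.5392 53.06698 1.211470e+00
25.2079 53.03772 1.102236e+00
26.9948 53.00949 1.003429e+00
28.9083 52.98248 9.140058e-01
30.9575 52.95680 8.330278e-01
33.1520 52.93317 7.596593e-01
35.5020 52.91029 6.931522e-01
38.0186 52.88886 6.328300e-01
40.7136 52.86886 5.780876e-01
43.5997 52.85026 5.283804e-01
46.6903 52.83354 4.832222e-01
50.0000 52.81754 4.421721e-01
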