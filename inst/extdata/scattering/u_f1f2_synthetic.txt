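# U 92 238.02890
2.0000 77.79133 2.936120e+00
2.1418 77.75655 2.741732e+00
2.2936 77.65644 2.560272e+00
2.4562 77.48764 2.390783e+00
2.6303 77.20708 2.232536e+00
2.8167 76.78569 2.084794e+00
3.0164 76.12385 1.946771e+00
3.2302 75.00211 1.817919e+00
3.4592 72.58299 1.697572e+00
3.7044 68.81748 1.315722e+01
3.9670 75.99227 1.228626e+01
4.2482 78.65675 1.147300e+01
4.5494 80.32975 1.071341e+01
4.8719 81.52676 1.000423e+01
5.2172 82.43608 9.342099e+00
5.5870 83.15089 8.723751e+00
5.9831 83.72944 8.146211e+00
6.4072 84.19080 7.607004e+00
6.8614 84.56556 7.103448e+00
7.3478 84.86919 6.633223e+00
7.8686 85.11874 6.194189e+00
8.4264 85.30937 5.784154e+00
9.0237 85.45271 5.401287e+00
9.6634 85.55148 5.043732e+00
10.3484 85.60619 4.709868e+00
11.0819 85.61449 4.398126e+00
11.8675 85.57678 4.106981e+00
12.7087 85.46603 3.835136e+00
13.6096 85.26503 3.581266e+00
13.8000 85.20894 3.531855e+00
14.5743 84.91269 3.344215e+00
15.6075 84.27788 3.122832e+00
16.0000 83.87132 3.046225e+00
16.7138 82.49444 2.916129e+00
17.8986 83.64175 7.483353e+00
19.1674 85.05300 6.779905e+00
20.0000 85.11416 6.378573e+00
20.5261 84.67508 6.145912e+00
21.9811 85.67750 9.495664e+00
23.5392 88.02907 8.548997e+00
25.2079 89.09997 7.699881e+00
26.9948 89.78384 6.938138e+00
28.9083 90.25119 6.254542e+00
30.9575 90.58114 5.640834e+00
33.1520 90.81943 5.089687e+00
35.5020 90.98532 4.594572e+00
38.0186 91.10075 4.149616e+00
40.7136 91.17849 3.749589e+00
43.5997 91.22787 3.389810e+00
46.6903 91.25946 3.066119e+00
50.0000 91.27098 2.774766e+00
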