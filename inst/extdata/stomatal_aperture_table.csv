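time_h,photoperiod,mean,se,n,letters
0,12L12D,44.46,0.42,3,c
3,12L12D,56.86,1.20,3,ab
6,12L12D,58.80,0.80,3,a
9,12L12D,54.65,0.98,3,b
12,12L12D,55.60,1.22,3,b
15,12L12D,34.29,2.19,3,e
18,12L12D,35.26,0.50,3,e
21,12L12D,41.77,0.32,3,d
24,12L12D,45.72,1.44,3,c
0,6L6D,45.18,0.51,3,b
3,6L6D,58.24,1.60,3,a
6,6L6D,58.72,0.69,3,a
9,6L6D,38.62,0.88,3,d
12,6L6D,38.43,1.62,3,d
15,6L6D,44.24,1.48,3,b
18,6L6D,42.97,0.62,3,bc
21,6L6D,41.67,0.86,3,c
24,6L6D,43.72,0.83,3,bc
0,24L,43.37,1.07,3,d
3,24L,55.26,0.93,3,ab
6,24L,58.86,2.46,3,a
9,24L,56.26,0.49,3,ab
12,24L,52.46,2.66,3,bc
15,24L,49.20,1.51,3,c
18,24L,45.60,0.98,3,d
21,24L,50.27,1.90,3,b
24,24L,52.52,1.53,3,bc
0,3L3D,43.62,1.39,3,ef
1.5,3L3D,48.14,0.27,3,bc
3,3L3D,56.20,1.04,3,a
4.5,3L3D,49.27,0.86,3,b
6,3L3D,43.96,0.80,3,def
7.5,3L3D,46.05,0.82,3,cde
9,3L3D,50.41,1.71,3,b
10.5,3L3D,39.22,0.87,3,h
12,3L3D,40.47,1.54,3,gh
13.5,3L3D,46.58,0.32,3,cd
15,3L3D,45.85,1.20,3,cde
16.5,3L3D,44.55,1.34,3,def
18,3L3D,40.21,1.92,3,h
19.5,3L3D,44.54,0.78,3,def
21,3L3D,45.48,0.81,3,def
22.5,3L3D,39.24,1.53,3,h
24,3L3D,42.83,1.31,3,fg
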