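22
1 23 1
2 8 0.0254589
2 12 0.0212987
2 17 0.118101
2 18 0.0438786
2 19 0.0438786
2 22 0.243453
2 23 0.503932
3 9 0.0320765
3 13 0.0259475
3 14 0.030422
3 16 0.114645
3 21 0.206003
3 23 0.590906
4 23 1
5 9 0.0563011
5 13 0.0447335
5 14 0.042655
5 16 0.071996
5 21 0.0531675
5 23 0.731147
6 10 0.0623399
6 11 0.0567964
6 15 0.10216
6 20 0.0498233
6 23 0.728881
7 13 0.0535438
7 14 0.0838121
7 16 0.0343063
7 21 0.0224765
7 23 0.805861
8 23 0.974541
9 15 0.0893502
9 20 0.0264622
9 23 0.79581
10 14 0.110613
10 16 0.0324339
10 21 0.0204501
10 23 0.774163
11 16 0.0379363
11 21 0.0204912
11 23 0.884776
12 23 0.978701
13 20 0.0328686
13 23 0.842907
14 20 0.0410302
14 23 0.691468
15 21 0.0549341
15 23 0.753556
16 20 0.0919886
16 23 0.616694
17 23 0.881899
18 23 0.956121
19 23 0.956121
20 23 0.757827
21 23 0.622478
22 23 0.756547
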