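# SWC: id type x y z radius parent (nm)
1 0 10000.00 10000.00 5000.00 40 -1
2 0 10482.52 9901.55 5086.51 40 1
3 0 10909.67 9835.79 5337.95 40 2
4 0 11173.04 9938.68 5750.32 40 3
5 0 11198.88 10007.47 6244.89 40 4
6 0 11683.12 10074.70 6349.74 40 5
7 0 11775.91 10558.94 6432.84 40 6
8 0 11588.62 10947.45 6685.78 40 7
9 0 11767.88 11336.32 6943.95 40 8
10 0 11640.70 11798.00 7087.72 40 9
11 0 11605.32 12234.02 7329.88 40 10
12 0 11475.42 12713.89 7276.50 40 11
13 0 11266.12 12973.17 6903.72 40 12
14 0 11086.28 13234.82 6517.46 40 13
15 0 11049.54 13339.60 6029.94 40 14
16 0 11130.48 13262.36 5542.62 40 15
17 0 11136.76 13305.69 5044.54 40 16
18 0 11010.26 13614.10 4671.87 40 17
19 0 10887.60 14009.09 4390.92 40 18
20 0 10700.24 13783.42 3985.99 40 19
21 0 10413.51 13563.20 3640.61 40 20
22 0 10356.92 13092.56 3481.55 40 21
23 0 10360.72 12592.59 3485.13 40 22
24 0 10454.22 12101.49 3476.35 40 23
25 0 10599.73 11628.97 3401.82 40 24
26 0 10894.79 11225.40 3409.74 40 25
27 0 10999.27 10780.75 3613.14 40 26
28 0 11152.04 10342.53 3799.21 40 27
29 0 11075.44 9891.48 4000.92 40 28
30 0 10958.06 9580.47 4374.42 40 29
31 0 11056.77 9272.14 4755.45 40 30
32 0 11319.85 8885.60 4932.59 40 31
33 0 11368.17 8408.64 5074.62 40 32
34 0 11363.87 9949.54 5162.57 40 3
35 0 11820.45 10060.41 4991.57 40 34
36 0 12286.46 10164.33 4843.12 40 35
37 0 12614.03 10177.81 4465.61 40 36
38 0 13066.85 10045.39 4631.19 40 37
39 0 13481.35 9835.86 4446.03 40 38
40 0 13662.01 9620.10 4032.73 40 39
41 0 13806.74 9386.80 3614.86 40 40
42 0 13639.71 9030.08 3306.88 40 41
43 0 13577.47 8622.73 3023.68 40 42
44 0 13707.15 8472.67 2564.70 40 43
45 0 13805.42 8526.86 2077.46 40 44
46 0 13873.96 8556.96 1583.10 40 45
47 0 13865.79 8578.95 1083.65 40 46
48 0 10740.26 9706.49 5844.07 40 4
49 0 10424.33 9319.30 5860.49 40 48
50 0 10027.31 9029.67 5768.34 40 49
51 0 9546.18 8966.60 5647.78 40 50
52 0 9064.70 8941.75 5515.27 40 51
53 0 8712.20 9152.21 5229.88 40 52
54 0 8349.82 9451.37 5059.04 40 53
55 0 8087.18 9742.05 4748.35 40 54
56 0 8116.82 10138.94 4445.70 40 55
57 0 7929.49 10565.10 4263.25 40 56
58 0 7763.30 10964.30 4012.20 40 57
59 0 7671.04 11373.43 3739.98 40 58
60 0 7419.39 11783.78 3604.76 40 59
61 0 6957.37 11936.20 3489.42 40 60
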