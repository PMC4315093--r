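chrom	bp_length	morgans
1	195000000	3.9
2	148000000	2.96
3	110000000	2.211
4	90000000	1.818
5	60000000	1.296
6	35000000	1.0045
7	38000000	1.0298
8	30000000	0.966
9	25000000	0.925
10	22000000	0.8976
11	21000000	0.8862
12	20000000	0.874
13	18000000	0.8478
14	15000000	0.7965
15	13000000	0.7514
16	500000	0.0535
17	11000000	0.6952
18	10500000	0.6794
19	10000000	0.662
20	14000000	0.7756
21	7000000	0.5348
22	4000000	0.3556
23	6000000	0.4818
24	6500000	0.5096
25	2000000	0.1976
26	5000000	0.4225
27	4800000	0.4099
28	4500000	0.3902
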