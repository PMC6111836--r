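week	date	hour	mean_bpm
1	2018-04-17	17	92.50
1	2018-04-17	18	84.00
1	2018-04-17	19	84.40
1	2018-04-19	21	118.36
1	2018-04-20	20	92.80
1	2018-04-20	23	96.00
1	2018-04-21	0	106.00
1	2018-04-21	1	99.64
1	2018-04-21	2	110.60
1	2018-04-22	16	102.00
1	2018-04-22	17	107.64
1	2018-04-22	20	100.00
2	2018-05-02	18	90.00
2	2018-05-02	19	81.64
2	2018-05-02	20	81.16
2	2018-05-02	21	83.64
2	2018-05-02	22	80.86
2	2018-05-03	21	107.36
2	2018-05-03	22	104.00
2	2018-05-04	19	99.25
2	2018-05-04	21	99.64
2	2018-05-04	22	103.60
2	2018-05-04	23	98.00
2	2018-05-05	0	103.50
2	2018-05-05	1	102.36
2	2018-05-06	0	86.50
2	2018-05-06	2	84.20
3	2018-05-07	16	78.64
3	2018-05-07	21	79.20
3	2018-05-08	22	88.40
3	2018-05-10	21	114.40
3	2018-05-11	18	89.36
3	2018-05-11	19	95.80
3	2018-05-11	20	93.25
3	2018-05-11	23	89.36
3	2018-05-12	23	85.00
3	2018-05-13	0	83.00
3	2018-05-13	1	77.50
3	2018-05-13	14	78.86
3	2018-05-13	15	76.00
4	2018-06-05	16	83.40
4	2018-06-05	17	83.50
4	2018-06-05	18	81.50
4	2018-06-06	16	77.20
4	2018-06-06	17	82.00
4	2018-06-08	20	92.25
4	2018-06-08	22	92.50
4	2018-06-09	14	92.00
4	2018-06-10	16	85.75
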