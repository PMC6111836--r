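week	date	max_bpm
1	2018-04-16	121.00
1	2018-04-17	97.00
1	2018-04-18	108.00
1	2018-04-19	134.00
1	2018-04-20	108.00
1	2018-04-21	119.00
1	2018-04-22	117.00
2	2018-04-30	110.00
2	2018-05-01	107.00
2	2018-05-02	91.00
2	2018-05-03	123.00
2	2018-05-04	117.00
2	2018-05-05	114.00
2	2018-05-06	98.00
3	2018-05-07	93.00
3	2018-05-08	97.00
3	2018-05-09	134.00
3	2018-05-10	130.00
3	2018-05-11	109.00
3	2018-05-12	100.00
3	2018-05-13	87.00
4	2018-06-04	103.00
4	2018-06-05	90.00
4	2018-06-06	89.00
4	2018-06-07	112.00
4	2018-06-08	101.00
4	2018-06-09	104.00
4	2018-06-10	94.00
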