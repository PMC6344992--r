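gene	n_obs	studies
Rps29	6	1,2,5,6,7,8
Ppp1r9b	6	1,2,3,6,7,8
Tpt1	6	1,2,4,5,7,8
Rpl37	5	1,2,5,7,8
Rpl17	5	1,2,5,6,8
Dlg4	5	1,2,3,6,8
Rpl4	5	1,2,4,7,8
Arl3	5	2,5,6,7,8
Map2	5	1,2,3,6,8
Rplp0	5	1,4,5,7,8
Psd	5	1,2,3,6,8
Rpl28	5	2,5,6,7,8
Rpl21	5	1,2,5,7,8
Arpc1b	5	1,4,5,7,8
Ftl1	5	1,2,4,5,8
Rps12	5	1,2,5,7,8
Eif3f	5	1,2,5,6,8
Uba52	5	1,2,5,7,8
Ube2m	5	1,2,5,6,8
Rpl32	4	1,5,7,8
Rpl31	4	1,2,5,8
Abhd17a	4	1,5,6,8
Fgf13	4	2,6,7,8
Rpl15	4	1,2,5,8
Rpl13	4	1,2,5,8
Rpl19	4	1,2,5,8
Ids	4	1,2,3,8
Serbp1	4	1,2,5,8
Sptbn2	4	1,2,6,8
Pacsin1	4	1,2,6,8
Hpcal4	4	1,2,3,6
Rtn2	4	1,5,6,8
Rnf165	4	1,2,6,8
Hint1	4	1,2,5,8
Eef2	4	1,2,4,8
Rpsa	4	1,2,5,8
Rps2	4	1,2,5,8
Rps8	4	2,5,7,8
Selenow	4	2,3,5,8
Camk2a	4	1,2,3,6
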