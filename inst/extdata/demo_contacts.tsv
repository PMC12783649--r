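# demo contact records (tab-separated)
# frame	interaction_type	atom_1	atom_2
0	hbbb	A:ARG:131:N	A:GLU:268:OE1
1	hbbb	A:ARG:131:N	A:GLU:268:OE1
1	sb	A:ASP:130:OD1	A:TYR:326:OH
2	hbbb	A:ARG:131:N	A:GLU:268:OE1
2	sb	A:ASP:130:OD1	A:TYR:326:OH
3	hbbb	A:ARG:131:N	A:GLU:268:OE1
3	sb	A:ASP:130:OD1	A:TYR:326:OH
4	hbbb	A:ARG:131:N	A:GLU:268:OE1
4	sb	A:ASP:130:OD1	A:TYR:326:OH
5	hbbb	A:ARG:131:N	A:GLU:268:OE1
6	hbbb	A:ARG:131:N	A:GLU:268:OE1
6	sb	A:ASP:130:OD1	A:TYR:326:OH
7	hbbb	A:ARG:131:N	A:GLU:268:OE1
8	hbbb	A:ARG:131:N	A:GLU:268:OE1
8	sb	A:ASP:130:OD1	A:TYR:326:OH
9	hbbb	A:ARG:131:N	A:GLU:268:OE1
10	hbbb	A:ARG:131:N	A:GLU:268:OE1
10	sb	A:ASP:130:OD1	A:TYR:326:OH
11	hbbb	A:ARG:131:N	A:GLU:268:OE1
11	sb	A:ASP:130:OD1	A:TYR:326:OH
12	hbbb	A:ARG:131:N	A:GLU:268:OE1
12	vdw	A:CYS:327:SG	A:PHE:332:CZ
13	hbbb	A:ARG:131:N	A:GLU:268:OE1
13	vdw	A:CYS:327:SG	A:PHE:332:CZ
13	sb	A:ASP:130:OD1	A:TYR:326:OH
14	hbbb	A:ARG:131:N	A:GLU:268:OE1
14	vdw	A:CYS:327:SG	A:PHE:332:CZ
15	vdw	A:CYS:327:SG	A:PHE:332:CZ
15	sb	A:ASP:130:OD1	A:TYR:326:OH
16	vdw	A:CYS:327:SG	A:PHE:332:CZ
17	vdw	A:CYS:327:SG	A:PHE:332:CZ
17	sb	A:ASP:130:OD1	A:TYR:326:OH
18	vdw	A:CYS:327:SG	A:PHE:332:CZ
19	vdw	A:CYS:327:SG	A:PHE:332:CZ
19	sb	A:ASP:130:OD1	A:TYR:326:OH
20	vdw	A:CYS:327:SG	A:PHE:332:CZ
21	vdw	A:CYS:327:SG	A:PHE:332:CZ
21	sb	A:ASP:130:OD1	A:TYR:326:OH
22	vdw	A:CYS:327:SG	A:PHE:332:CZ
23	vdw	A:CYS:327:SG	A:PHE:332:CZ
24	vdw	A:CYS:327:SG	A:PHE:332:CZ
25	vdw	A:CYS:327:SG	A:PHE:332:CZ
25	sb	A:ASP:130:OD1	A:TYR:326:OH
26	vdw	A:CYS:327:SG	A:PHE:332:CZ
27	vdw	A:CYS:327:SG	A:PHE:332:CZ
28	vdw	A:CYS:327:SG	A:PHE:332:CZ
29	vdw	A:CYS:327:SG	A:PHE:332:CZ
29	sb	A:ASP:130:OD1	A:TYR:326:OH
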