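id	chr	pos	z	n
rs0001	1	1e+05	0.2335	4000
rs0002	1	102500	0.9843	4000
rs0003	1	105000	4.835	4000
rs0004	1	107500	1.851	4000
rs0005	1	110000	1.3414	4000
rs0006	1	112500	1.3414	4000
rs0007	1	115000	0.8953	4000
rs0008	1	117500	6.8467	4000
rs0009	1	120000	3.2583	4000
rs0010	1	122500	-0.1801	4000
rs0011	1	125000	-0.5205	4000
rs0012	1	127500	-1.7038	4000
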