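chrK	3000	3300	V1|V|DEL|3299	0	+
chrK	5000	5300	V2|V|INV|5000	0	-
chrK	7000	7300	V3|V|DEL|7299	0	+
chrK	10000	10300	V4|V|DEL|10299	0	+
chrK	12000	12300	V5|V|INV|12000	0	-
chrK	14000	14300	V6|V|DEL|14299	0	+
chrK	17000	17300	V7|V|DEL|17299	0	+
chrK	19000	19300	V8|V|INV|19000	0	-
chrK	21000	21300	V9|V|DEL|21299	0	+
chrK	24000	24300	V10|V|DEL|24299	0	+
chrK	26000	26300	V11|V|INV|26000	0	-
chrK	28000	28300	V12|V|DEL|28299	0	+
chrK	30500	30800	J1|J||30500	0	+
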