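time	mean	Vp	n	se
7	12.701830927198328	400	4	10
181	10.84979494238112	400	17	4.8507125007266598
262	26.790340203627849	400	59	2.6037782196164772
387	41.571509662869765	400	56	2.6726124191242437
478	47.932778259718745	400	19	4.5883146774112351
509	46.689049836843864	400	7	7.5592894601845444
624	63.149325034327809	400	23	4.1702882811414952
738	70.231115219302794	400	60	2.5819888974716112
812	84.999498202703634	400	14	5.3452248382484875
921	96.210218351730191	400	31	3.5921060405354979
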