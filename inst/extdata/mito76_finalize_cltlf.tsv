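config	rank_k	isolates_control	cltlf
06clusters	3	TRUE	100
06clusters	3	TRUE	243
06clusters	3	TRUE	45
06clusters	3	TRUE	96
06clusters	3	TRUE	13
06clusters	3	TRUE	40
06clusters	6	TRUE	100
06clusters	6	TRUE	243
06clusters	6	TRUE	64
06clusters	6	TRUE	100
06clusters	6	TRUE	13
06clusters	6	TRUE	40
08clusters	6	TRUE	100
08clusters	6	TRUE	200
08clusters	6	TRUE	56
08clusters	6	TRUE	13
08clusters	6	TRUE	100
08clusters	6	TRUE	45
08clusters	6	TRUE	24
08clusters	6	TRUE	40
08clusters	9	TRUE	100
08clusters	9	TRUE	225
08clusters	9	TRUE	56
08clusters	9	TRUE	56
08clusters	9	TRUE	24
08clusters	9	TRUE	40
08clusters	9	TRUE	48
08clusters	9	TRUE	13
08clusters	12	FALSE	248
08clusters	12	FALSE	13
08clusters	12	FALSE	180
08clusters	12	FALSE	30
08clusters	12	FALSE	13
08clusters	12	FALSE	32
08clusters	12	FALSE	13
08clusters	12	FALSE	13
08clusters	45	TRUE	100
08clusters	45	TRUE	243
08clusters	45	TRUE	13
08clusters	45	TRUE	136
08clusters	45	TRUE	22
08clusters	45	TRUE	13
08clusters	45	TRUE	13
08clusters	45	TRUE	13
10clusters	30	FALSE	144
10clusters	30	FALSE	252
10clusters	30	FALSE	13
10clusters	30	FALSE	13
10clusters	30	FALSE	56
10clusters	30	FALSE	13
10clusters	30	FALSE	13
10clusters	30	FALSE	13
10clusters	30	FALSE	13
10clusters	30	FALSE	13
12clusters	12	TRUE	100
12clusters	12	TRUE	216
12clusters	12	TRUE	13
12clusters	12	TRUE	64
12clusters	12	TRUE	22
12clusters	12	TRUE	13
12clusters	12	TRUE	16
12clusters	12	TRUE	24
12clusters	12	TRUE	40
12clusters	12	TRUE	48
12clusters	12	TRUE	13
12clusters	12	TRUE	13
14clusters	18	TRUE	100
14clusters	18	TRUE	240
14clusters	18	TRUE	13
14clusters	18	TRUE	90
14clusters	18	TRUE	22
14clusters	18	TRUE	13
14clusters	18	TRUE	16
14clusters	18	TRUE	24
14clusters	18	TRUE	40
14clusters	18	TRUE	13
14clusters	18	TRUE	13
14clusters	18	TRUE	13
14clusters	18	TRUE	13
14clusters	18	TRUE	13
14clusters	21	TRUE	100
14clusters	21	TRUE	250
14clusters	21	TRUE	13
14clusters	21	TRUE	88
14clusters	21	TRUE	22
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	21	TRUE	30
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	21	TRUE	13
14clusters	36	FALSE	88
14clusters	36	FALSE	240
14clusters	36	FALSE	13
14clusters	36	FALSE	96
14clusters	36	FALSE	22
14clusters	36	FALSE	20
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	36	FALSE	13
14clusters	60	TRUE	100
14clusters	60	TRUE	220
14clusters	60	TRUE	13
14clusters	60	TRUE	112
14clusters	60	TRUE	22
14clusters	60	TRUE	20
14clusters	60	TRUE	13
14clusters	60	TRUE	24
14clusters	60	TRUE	13
14clusters	60	TRUE	13
14clusters	60	TRUE	13
14clusters	60	TRUE	13
14clusters	60	TRUE	13
14clusters	60	TRUE	13
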