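algorithm	rank_k	cltlf
kmeans	60	100
kmeans	60	140
kmeans	60	48
kmeans	60	56
kmeans	60	26
kmeans	60	60
kmeans	60	45
kmeans	60	99
asap	60	100
asap	60	243
asap	60	13
asap	60	136
asap	60	22
asap	60	13
asap	60	13
asap	60	13
kmeans	9	100
kmeans	9	140
kmeans	9	48
kmeans	9	40
kmeans	9	81
kmeans	9	40
kmeans	9	60
kmeans	9	64
asap	9	100
asap	9	225
asap	9	56
asap	9	56
asap	9	24
asap	9	40
asap	9	48
asap	9	13
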