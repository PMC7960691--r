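state	severity	ringing	db_low	db_high	weight	lower	upper
normal	normal	FALSE	0	20	0	0	0
mild	mild	FALSE	20	35	0.010	0.004	0.019
mild_ringing	mild	TRUE	20	35	0.021	0.012	0.036
moderate	moderate	FALSE	35	50	0.027	0.015	0.042
moderate_ringing	moderate	TRUE	35	50	0.074	0.048	0.107
moderately_severe	moderately severe	FALSE	50	65	0.092	0.064	0.129
moderately_severe_ringing	moderately severe	TRUE	50	65	0.167	0.114	0.231
severe	severe	FALSE	65	80	0.158	0.104	0.227
severe_ringing	severe	TRUE	65	80	0.261	0.174	0.361
profound	profound	FALSE	80	95	0.204	0.134	0.288
profound_ringing	profound	TRUE	80	95	0.277	0.182	0.388
complete	complete	FALSE	95	Inf	0.215	0.143	0.307
complete_ringing	complete	TRUE	95	Inf	0.316	0.211	0.436
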