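target	rank_sum_poag	rank_sum_ctrl	n_poag	n_ctrl	u_printed	z_printed	z_adjusted_printed
PPP2R2B	14078	14842	120	120	6818	-0.710	-0.712
TARS	16741	12179	120	120	4919	4.242	4.258
C1QBP	15714	13206	120	120	5946	2.332	2.333
PNMA2	16032	12888	120	120	5628	2.923	2.930
MCTS1	15015	13905	120	120	6645	1.032	1.034
HSPD1	16793	12127	120	120	4867	4.338	4.350
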