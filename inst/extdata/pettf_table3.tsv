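# columns: pair_id, ka, ks, ratio, t_my
pair_id	ka	ks	ratio	t_my
PeTTF2-10	0.19628	0.28456	0.6898	21.89
PeTTF3-23	0.3001	0.57003	0.5265	43.85
PeTTF4-21	0.40385	0.30886	1.3076	23.76
PeTTF5-14	0.24701	0.26566	0.9298	20.44
PeTTF7-16	2.05006	1.33589	1.5346	102.76
PeTTF15-26	0.37904	0.7751	0.4890	59.62
PeTTF18-32	0.22935	0.26615	0.8617	20.47
PeTTF19-25	2.3437	1.19812	1.9561	92.16
PeTTF20-22	0.03489	0.15364	0.2271	11.82
PeTTF24-31	0.06509	0.10698	0.6084	8.22
PeTTF27-30	0.03282	0.0955	0.3437	7.35
PeTTF33-35	1.26582	0.53139	2.3821	40.88
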