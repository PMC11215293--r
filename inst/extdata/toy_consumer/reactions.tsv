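id	equation	lb	ub	objective
EX_gB_e	gB_e <=> 	             -1000	              1000	                 0
T_gB	gB_e --> c_c	                 0	              1000	                 0
BIOMASS	c_c --> 	                 0	              1000	                 1
EX_byp_e	byp_e <=> 	             -1000	              1000	                 0
U_byp	byp_e --> c_c	                 0	              1000	                 0
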