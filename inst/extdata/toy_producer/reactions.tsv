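id	equation	lb	ub	objective
EX_gA_e	gA_e <=> 	             -1000	              1000	                 0
T_gA	gA_e --> c_c	                 0	              1000	                 0
BIOMASS	c_c --> 0.10000000000000001 byp_c	                 0	              1000	                 1
T_byp	byp_c --> byp_e	                 0	              1000	                 0
EX_byp_e	byp_e <=> 	             -1000	              1000	                 0
CONV	c_c -->                0.5 byp_c	                 0	              1000	                 0
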