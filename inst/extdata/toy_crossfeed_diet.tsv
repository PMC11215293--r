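# name: toy_crossfeed_oneway
# default_policy: unconstrained
metabolite_id	lower	upper
gA_e	               -10	              1000
gB_e	               -10	              1000
byp_e	                 0	              1000
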