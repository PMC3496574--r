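probe_id	rsid	gene	note
Probe1	rs1152003	ABCB4	
Probe2	rs10893	CYP2D6	example ADME marker
Probe3		ABCC5	
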