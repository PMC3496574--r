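ProbeID	Subject1	Subject2	Subject3	Subject4
Class	A	A	B	B
Probe1	C/C	C/C	T/T	T/T
Probe2	G/C	C/C	-/T	A/A
Probe3	C/T	C/T	C/T	C/T
Probe4	G/G	A/G	G/G	G/G
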