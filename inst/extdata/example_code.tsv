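id	sequence
BC001	TTCC
BC002	ACAC
BC003	CGAA
BC004	TAGG
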