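{"metric":"seqlev","dmin":3,"n":4,"k":1,"context_k":1,"size":4,"policy":{"gc_min":0.4,"gc_max":0.6,"max_homopolymer_run":2,"reject_self_reverse_complement":true}}
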