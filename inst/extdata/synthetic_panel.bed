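chrS	0	106	amp01	0	.
chrS	1000	1138	amp02	0	.
chrS	2000	2141	amp03	0	.
chrS	3000	3124	amp04	0	.
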