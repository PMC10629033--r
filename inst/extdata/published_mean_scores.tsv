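method	mean_alignment_score
multilayer_embedding	0.608
temporal	0.483
static	0.047
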