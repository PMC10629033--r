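cell	count
both_correct	61
case_only_misaligned	8
control_only_correct	31
both_misaligned	0
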