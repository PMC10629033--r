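method	noise	n	mean	sd	se	cv
multilayer_embedding	10	10	0.60244	0.17505	0.05536	0.29057
multilayer_embedding	15	10	0.48106	0.13728	0.04341	0.28537
multilayer_embedding	20	10	0.50591	0.16227	0.05132	0.32076
multilayer_embedding	25	10	0.31792	0.12020	0.03801	0.37809
multilayer_embedding	5	10	0.74094	0.20141	0.06369	0.27183
static	10	10	0.05804	0.04241	0.01341	0.73064
static	15	10	0.03564	0.03300	0.01043	0.92582
static	20	10	0.04705	0.02963	0.00937	0.62980
static	25	10	0.04134	0.03068	0.00970	0.74203
static	5	10	0.04847	0.04152	0.01313	0.85647
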