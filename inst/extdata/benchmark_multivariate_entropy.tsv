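method	subject	accuracy_pct	accuracy_sd_pct	kappa_printed
mvMFE	aa	75.54	1.70	0.5108
mvMFE	al	86.00	0.98	0.7200
mvMFE	av	74.46	1.54	0.4928
mvMFE	aw	84.07	1.52	0.6814
mvMFE	ay	79.32	1.24	0.5864
RCmvMFE	aa	93.82	1.48	0.8764
RCmvMFE	al	98.46	0.61	0.9692
RCmvMFE	av	95.86	1.01	0.9172
RCmvMFE	aw	98.79	0.72	0.9794
RCmvMFE	ay	97.04	0.79	0.9408
IRCmvMFE	aa	99.39	0.38	0.9928
IRCmvMFE	al	99.71	0.15	0.9942
IRCmvMFE	av	98.61	0.62	0.9722
IRCmvMFE	aw	99.61	0.26	0.9942
IRCmvMFE	ay	99.82	0.35	0.9986
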