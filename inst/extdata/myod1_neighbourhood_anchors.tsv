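gene	state	tier
Igll1	up	array_reported
TargetB_syn	down	qrt_confirmed
RegulatorA_syn	up	qrt_confirmed
Gpc1	up	predicted
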