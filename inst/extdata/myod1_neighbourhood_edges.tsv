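source	target	sign	directness	provenance
Myod1	Igll1	+1	direct	figure-curated
Myod1	TargetB_syn	+1	direct	synthetic placeholder
RegulatorA_syn	Myod1	-1	direct	synthetic placeholder
Gpc1	Myod1	+1	indirect	figure-curated
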