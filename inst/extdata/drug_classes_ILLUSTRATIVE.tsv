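class_id	drug
cyp2d6_strong_inhibitors	fluoxetine
cyp2d6_strong_inhibitors	paroxetine
cyp2d6_strong_inhibitors	quinidine
cyp2d6_strong_inhibitors	bupropion
cyp2d6_substrates	atomoxetine
cyp2d6_substrates	codeine
cyp2d6_substrates	metoprolol
cyp2d6_substrates	tamoxifen
cyp2d6_substrates	dextromethorphan
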