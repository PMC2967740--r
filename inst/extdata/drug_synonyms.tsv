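alias	canonical
gleevec	imatinib mesylate
imatinib	imatinib mesylate
plavix	clopidogrel
prozac	fluoxetine
fluoxetine hcl	fluoxetine
strattera	atomoxetine
celebrex	celecoxib
coumadin	warfarin
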