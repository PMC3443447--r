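wing	morph	section	color
forewing	petiverana	proximal	black
forewing	petiverana	medial	red
forewing	petiverana	distal	black
forewing	hybrid	proximal	red
forewing	hybrid	medial	yellow
forewing	hybrid	distal	black
hindwing	emma	whole	red
hindwing	favorinus	whole	yellow
hindwing	amphitrite	whole	black
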