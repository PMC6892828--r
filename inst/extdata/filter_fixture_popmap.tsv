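AB1	AB
AB2	AB
AB3	AB
BG1	BG
BG2	BG
BG3	BG
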