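"endpoint","arm","events"
"OS","intervention",21
"PFS","intervention",74
"OS","control",38
"PFS","control",117
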