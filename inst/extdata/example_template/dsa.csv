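"parameter","low","high"
"hr_os",0.385,0.715
"hr_pfs",0.196,0.364
"discount_rate",0,0.05
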