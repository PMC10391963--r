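"name","unit_cost","dsa_low","dsa_high"
"drug_intervention",2194,1097,2194
"drug_control",2720,1360,2720
"next_line",0,0,3000
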