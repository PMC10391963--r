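"name","arm","quantity","unit","phase_start","phase_end","phase_unit","txcycle_length_weeks","cap"
"drug_intervention","intervention",3.78,"every-3-weeks",0,NA,"week",NA,NA
"drug_control","control",2.52,"every-3-weeks",0,NA,"week",NA,NA
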