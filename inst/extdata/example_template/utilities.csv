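"parameter","value"
"u_pfs_intervention",1
"u_pfs_control",1
"u_pps",1
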