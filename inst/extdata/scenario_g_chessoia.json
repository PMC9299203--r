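{"name":"protection removed, mining rights granted","description":"Worst case: MPA removed, treaty dissolved, licenses granted.","overrides":{"SGSSI_MPA":"EXPLORATION_LICENSE","ANTARCTIC_TREATY":"EXPLORATION_LICENSE"}}
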