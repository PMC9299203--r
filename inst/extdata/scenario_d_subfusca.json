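{"name":"exploitative mining commences at Longqi","description":"ISA allows exploitation; all known habitat removed.","overrides":{"ISA_COMRA_SWIR":"ACTIVE_MINING"}}
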