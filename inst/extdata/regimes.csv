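"management_area_id","regime","jurisdiction","notes"
"SGSSI_MPA","PROTECTED_EFFECTIVE","SGSSI MPA",NA
"ANTARCTIC_TREATY","PROTECTED_EFFECTIVE","Madrid Protocol, Antarctic Treaty",NA
"ISA_COMRA_SWIR","EXPLORATION_LICENSE","ISA",NA
"EEZ_PNG","EXPLORATION_LICENSE","EEZ:Papua New Guinea",NA
"EEZ_FIJI","UNPROTECTED_NO_LICENSE","EEZ:Fiji",NA
"EEZ_TONGA","UNPROTECTED_NO_LICENSE","EEZ:Tonga",NA
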