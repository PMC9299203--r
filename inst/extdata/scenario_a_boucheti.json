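{"name":"regional deep-sea mining moratorium enacted","description":"Pacific Island countries impose a regional moratorium.","overrides":{"EEZ_PNG":"PROTECTED_EFFECTIVE","EEZ_FIJI":"PROTECTED_EFFECTIVE","EEZ_TONGA":"PROTECTED_EFFECTIVE"}}
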