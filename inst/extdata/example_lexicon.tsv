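联苯双酯片	DRN
联苯双酯	COM
恶心	ADR
皮疹	ADR
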