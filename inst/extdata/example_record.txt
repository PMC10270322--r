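联苯双酯片:联苯双酯。个别病例服用后可出现轻度恶心,偶有皮疹。
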