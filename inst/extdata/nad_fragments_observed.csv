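mz
664.1167
542.0683
524.0577
428.0365
232.0827
136.0617
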