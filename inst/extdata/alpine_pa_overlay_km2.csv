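quantity,km2
multispecies_type1_refugia,14865
inside_protected_areas,6491
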