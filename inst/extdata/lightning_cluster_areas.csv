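cluster,area_ha,source
7,4668,lightning
other,2098,lightning
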