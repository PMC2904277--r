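# Pure water: no osmotically active components.
label: water
volume_L: 0.5
components: []
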