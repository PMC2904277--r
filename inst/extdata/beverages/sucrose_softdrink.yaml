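# Sucrose soft drink: 13.3% sucrose, labelled 400 mosm/L (ideal arithmetic
# on 133 g/L gives ~389; the declared value takes precedence).
label: sucrose soft drink
volume_L: 0.5
declared_osmolarity_mosm_L: 400
components:
  - solute: sucrose
    concentration_g_L: 133.0
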