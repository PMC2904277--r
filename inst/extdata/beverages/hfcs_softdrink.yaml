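# HFCS soft drink at 800 mosm/L: 144.128 g/L total monosaccharide at the
# typical 55% fructose / 45% glucose split, i.e. fructose 440 and glucose
# 360 mosm/L by ideal arithmetic (both 180.16 g/mol).
label: HFCS soft drink
volume_L: 0.5
declared_osmolarity_mosm_L: 800
components:
  - solute: glucose
    concentration_g_L: 64.8576
  - solute: fructose
    concentration_g_L: 79.2704
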