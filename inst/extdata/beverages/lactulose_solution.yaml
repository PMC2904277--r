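# Hypertonic lactulose solution (136.92 g/L -> 400 mosm/L): a persistent
# luminal osmotic load; its water is carried to the colon, never absorbed.
label: lactulose solution
volume_L: 0.2
components:
  - solute: lactulose
    concentration_g_L: 136.92
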