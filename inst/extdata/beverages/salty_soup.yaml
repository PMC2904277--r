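# Salty commercial soup: 1.3% NaCl, labelled 400 mosm/L.
# The declared value takes precedence over ideal arithmetic (13 g/L would
# compute to ~445 mosm/L).
label: salty commercial soup
volume_L: 0.5
declared_osmolarity_mosm_L: 400
components:
  - solute: nacl
    concentration_g_L: 13.0
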