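# Default physiology parameters of the homeostasis loop.  The underlying
# model is qualitative about every gain and time constant; these values are
# illustrative defaults chosen so the baseline MAP surrogate is 93 mmHg and
# a 3-drinks/day 800 mosm/L schedule settles a few mmHg above it.  Units in
# the field names' documentation (?physiology_params).
v_ecf0: 15.0
v_circ0: 3.0
na_conc: 140.0
na_intake_basal: 150.0
water_intake_basal: 1.5
gut_na_bypass: 0.4
k_aldo: 1.0
k_adh: 1.0
aldo_saturation: 2.0
tau_colon: 2.0
window_days: 3.0
c0: 20.0
c_gain: 500.0
k_renal: 0.5
na_set_gain: 50.0
beta_bp: 2.0
map0: 93.0
fast_completion_h: 2.0
fructose_completion_h: 4.0
noise_sd: 0.0
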