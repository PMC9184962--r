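# Time-delayed negative-feedback mitotic oscillator (frog egg extract).
# Rates per minute; concentrations dimensionless a.u.
# provenance: reference parameter set, column model1
ksy_cycb  = 0.04
kde1_cycb = 0.02
kde2_cycb = 0.4
kph_gwl   = 0.2
kdp1_gwl  = 0.08
kph_apc   = 0.2
kdp_apc   = 0.08
# provenance: reference constants, oscillator time-course panel
Jph_kin   = 0.01
Jdp_kin   = 0.01
Jph_apc   = 0.1
Jdp_apc   = 0.1
PP        = 1
Kin_tot   = 1
APC_tot   = 1
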