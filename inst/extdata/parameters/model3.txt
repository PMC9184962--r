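# As model2, with B55-mediated Greatwall dephosphorylation (bistable APC/C).
# provenance: reference parameter set, column model3
ksy_cycb  = 0.04
kde1_cycb = 0.02
kde2_cycb = 0.5
kph_gwl   = 2
kdp1_gwl  = 2
kdp2_gwl  = 20
kph_apc   = 1
kdp_apc   = 20
kph_ensa  = 1
kcat      = 1
kas1      = 10
kdi1      = 0.1
# provenance: reference constants, bistable-APC time-course panel
Km_tqssa  = 0.0026
deUb      = 0.5
# provenance: global totals shared by all switch models
PP        = 1
Gwl_tot   = 1
APC_tot   = 1
Cdc20_tot = 1
B55_tot   = 1
ENSA_tot  = 4
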