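# Dual-bistable network: Wee1/Cdc25 tyrosine-phosphorylation switch on MPF
# plus the Greatwall/ENSA/B55 switch on APC/C.
# provenance: reference parameter set, column model4
ksy_cycb  = 0.04
kde1_cycb = 0.02
kde2_cycb = 1
kde3_cycb = 0
kph_gwl   = 2
kdp1_gwl  = 0.5
kdp2_gwl  = 20
kph_apc   = 1
kdp_apc   = 20
kph_ensa  = 1
kcat      = 1
kas1      = 10
kdi1      = 0.1
kph1_cdk  = 0.02
kph2_cdk  = 2
kdp1_cdk  = 0.2
kdp2_cdk  = 2
# provenance: reference constants, dual-switch time-course panel
Km_tqssa  = 0.0026
deUb      = 0.5
CAP       = 0.3
# provenance: global totals shared by all switch models
PP        = 1
Gwl_tot   = 1
APC_tot   = 1
Cdc20_tot = 1
B55_tot   = 1
ENSA_tot  = 4
Wee1_tot  = 1
Cdc25_tot = 1
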