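# Greatwall/ENSA/B55 coherent feed-forward loop driving APC/C.
# provenance: reference parameter set, column model2
ksy_cycb  = 0.04
kde1_cycb = 0.02
kde2_cycb = 2
kph_gwl   = 0.1
kdp1_gwl  = 0.2
kph_apc   = 1
kdp_apc   = 20
kph_ensa  = 0.2
kcat      = 0.1
kas1      = 10
kdi1      = 0.1
# provenance: reference constants, feed-forward time-course panel
Km_tqssa  = 0.0008
deUb      = 0.75
# provenance: global totals shared by all switch models
PP        = 1
Gwl_tot   = 1
APC_tot   = 1
Cdc20_tot = 1
B55_tot   = 1
ENSA_tot  = 4
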