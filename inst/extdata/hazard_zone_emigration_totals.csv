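zone,emig_total_thousand,emig_black_thousand
below_1m,169,98
below_3m,226,119
below_1m_excl_new_orleans,68,15
below_3m_excl_new_orleans,116,24
coastal_100yr_floodplain,78,26
inland_100yr_floodplain,243,47
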