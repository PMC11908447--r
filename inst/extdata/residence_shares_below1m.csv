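zone,black_share_zone,black_share_national
below_1m,0.195,0.12
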