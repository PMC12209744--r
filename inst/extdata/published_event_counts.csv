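group,n_total,n_no_event
ifn_low,82,72
ifn_high,67,30
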