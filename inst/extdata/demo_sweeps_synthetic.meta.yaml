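frequency_hz: 20.0
baseline_sd_pa: 2.0
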