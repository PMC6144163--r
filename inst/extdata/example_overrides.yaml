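# Example parameter-override file: any key not listed falls back to the
# packaged defaults. See ?load_params for the full key set.
self_quit: 0.02
discount_rate: 0.015
include_cancer_cost: false
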