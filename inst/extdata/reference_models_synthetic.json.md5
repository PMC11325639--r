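5328e90464f368f76a8cd5de3f3b6c31 reference_models_synthetic.json
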