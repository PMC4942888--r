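# one planted dilemma pair plus background constructs
n_other_elements = 12
background_constructs = 2
seed = 42
plant = implicative_dilemma target_r=0.8
plant = dilemmatic dilemmatic_self=3
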