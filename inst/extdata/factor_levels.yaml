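# Three-level full-factorial design: factor levels (ascending = l, m, h)
alpha: [10, 14, 20]   # initial glucose, g/l
beta: [0.2, 0.5, 1.0] # initial dye, g/l
gamma: [1, 2, 3]      # bacterial inoculation day, d
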