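8 4
toxoplasma 1.0 0.05 0.0 0.0
gondii 0.9 0.1 0.0 0.0
heart 0.0 1.0 0.0 0.05
cardiac 0.05 0.9 0.1 0.0
sugar 0.0 0.0 1.0 0.05
glucose 0.0 0.1 0.9 0.0
fever 0.0 0.05 0.0 1.0
pyrexia 0.1 0.0 0.05 0.9
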