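# MHC class II signature: class II alpha/beta chains plus the
# invariant chain
H2-Ab1
H2-Eb1
H2-Aa
Cd74
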