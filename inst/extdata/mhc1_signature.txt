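# MHC class I signature: classical class Ia heavy/light chains and
# the ER peptide transporter
H2-K1
H2-D1
B2m
Tap1
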