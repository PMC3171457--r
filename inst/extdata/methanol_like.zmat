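# Methanol-like synthetic fixture: 6 atoms, body-fixed Z-matrix (Angstrom/degrees).
# The hydroxyl rotation phi6 is the unconstrained coordinate; all other
# internals are flexibly constrained.
H
C 1 1.0900000000
O 2 1.4200000000 1 109.5000000000
H 2 1.0900000000 3 109.4000000000 1 120.0000000000 phase
H 2 1.0900000000 3 109.4000000000 1 -120.0000000000 phase
H 3 0.9600000000 2 108.5000000000 1 180.0000000000 principal

unconstrained: phi6
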