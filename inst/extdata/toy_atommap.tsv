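R1	A[c] (ab) -> B[c] (ab)
R2	B[c] (ab) -> C[c] (a) + D[c] (b)
R3	D[c] (b) ->
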