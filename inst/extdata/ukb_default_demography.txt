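# Four-epoch caricature of north-west European demographic history.
# Columns: start_generation (before present)  diploid_N
start_generation diploid_N
0 500000
100 10000
2400 3000
2500 14000
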