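# Electron-ion interaction potential (EIIP) of the four DNA nucleotides, in
# Rydbergs. Source: Veljkovic V, Slavic I (1972) Phys Rev Lett 29:105; as used
# in the Resonant Recognition Model literature (Cosic 1994).
residue,value
A,0.1260
C,0.1340
G,0.0806
T,0.1335
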