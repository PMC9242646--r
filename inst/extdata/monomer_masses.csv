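# Monomer masses (kDa) of the purified constructs, derived from the
# construct amino-acid sequences (average residue masses).
construct,mass_kda
NCC,38.45
LIC1,56.6
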