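# Distances must be bit-identical to the plain R oracle expression:
# forbid fused multiply-add contraction of dx*dx + dy*dy + dz*dz.
PKG_CXXFLAGS = -ffp-contract=off
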