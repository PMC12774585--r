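# crisprDonor default guide-efficiency position-weight matrix
# PROVENANCE: synthetic stand-in, hand-set by the crisprDonor authors.
# It encodes generic positional base preferences (mild GC preference in
# the PAM-proximal seed, penalty for T at the PAM-proximal end, slight
# bonus for a 5' G) so that ranking is deterministic and reproducible.
# It is NOT a trained model and does not reproduce the numeric output of
# any published efficiency predictor. Rows = protospacer positions 1..20
# (1 = PAM-distal, 20 = PAM-proximal); columns = A C G T.
A C G T
0.25 0.24 0.32 0.19
0.25 0.25 0.26 0.24
0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25
0.25 0.25 0.25 0.25
0.24 0.26 0.26 0.24
0.24 0.26 0.26 0.24
0.24 0.26 0.26 0.24
0.24 0.26 0.26 0.24
0.23 0.27 0.27 0.23
0.23 0.27 0.27 0.23
0.23 0.27 0.27 0.23
0.23 0.27 0.27 0.23
0.22 0.28 0.28 0.22
0.22 0.28 0.28 0.22
0.21 0.29 0.29 0.21
0.20 0.30 0.30 0.20
0.18 0.30 0.34 0.18
0.15 0.28 0.45 0.12
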