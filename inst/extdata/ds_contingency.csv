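grade,positives,negatives
G0,0,2
G1,0,8
G2,6,4
G3,61,30
G4,14,1
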