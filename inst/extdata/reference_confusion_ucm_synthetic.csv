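true_class,Benign,Malignant,Normal
Benign,59,4,7
Malignant,4,64,2
Normal,4,3,63
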