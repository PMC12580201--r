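class,precision,sensitivity,specificity,f1
Benign,82.98,79.59,92.31,81.25
Malignant,96.08,100.00,98.31,98.00
Normal,83.67,83.67,92.31,83.67
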