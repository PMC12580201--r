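class,precision,sensitivity,specificity,f1
Benign,88.06,84.29,94.29,86.13
Malignant,90.14,91.43,95.00,90.78
Normal,87.50,90.00,93.57,88.73
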