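model,correct,n
ensemble,186,210
DenseNet121,166,210
VGG16,162,210
MobileNetV2,158,210
LVM,157,210
VGG19,149,210
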