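name,target_mz,tolerance_da,formula,charge
budesonide,564.308,0.005,C32H42N3O6,1
internal_standard,568.283,0.005,C31H39FN3O6,1
heme,616.176,0.005,C34H32FeN4O4,1
spc,4188,1.0,,
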