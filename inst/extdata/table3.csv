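patient,ieoa_mri_cm2_m2,ieoa_as_cm2_m2
I,0.74,1.07
II,0.73,1.14
III,0.59,0.85
IV,0.62,0.80
V,0.91,1.10
VI,0.84,0.96
VII,0.66,0.87
VIII,0.70,0.96
IX,1.00,1.11
X,0.76,0.92
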