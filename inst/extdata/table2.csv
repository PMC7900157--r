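patient,size_vi_mm,size_as_mm,q_peak_ml_s,reynolds
I,23,23,354,6997
II,29,27,430,7240
III,25,25,394,7164
IV,25,23,539,10653
V,25,23,367,7253
VI,25,23,235,4645
VII,27,23,407,8044
VIII,25,21,296,6407
IX,25,25,412,7491
X,23,25,464,8437
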