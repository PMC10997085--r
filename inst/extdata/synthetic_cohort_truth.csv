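individual,true_sex,mean_depth
ind001,female,14
ind002,female,14
ind003,female,14
ind004,male,14
ind005,male,14
ind006,male,14
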