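wavelength_nm,n,k
548.6,0.43,2.455
582.1,0.29,2.863
616.8,0.21,3.272
659.5,0.14,3.697
704.5,0.13,4.103
756.0,0.14,4.542
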