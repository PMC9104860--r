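material,n
bk7,1.52
pmma,1.489
water,1.33
air,1.0
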