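name,mass_delta,charge
[M+H]+,1.00727645,1
[M+Na]+,22.98922070,1
[M-H2O+H]+,-17.00328823,1
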