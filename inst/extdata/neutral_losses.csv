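name,mass
H2O,18.010565
CO,27.994915
hexose,162.052824
deoxyhexose,146.057909
caffeoyl,162.031694
malonyl,86.000394
glucuronyl,176.032088
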