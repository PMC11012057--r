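class,dpi_mz,tolerance_ppm
caffeoylquinic,163.03897,10
luteolin,287.05501,10
apigenin,271.06009,10
diosmetin,301.07037,10
acacetin,285.07574,10
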