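scenario,zone,area_km2
current,conversion,1597.95
current,diversification,4391.77
current,expansion,532394.94
current,intensification,73834.26
current,not_recommended,131843.07
RCP4.5,conversion,15505.92
RCP4.5,diversification,46419.80
RCP4.5,expansion,279644.67
RCP4.5,intensification,53157.47
RCP4.5,not_recommended,349334.13
RCP8.5,conversion,56593.59
RCP8.5,diversification,64436.06
RCP8.5,expansion,129174.18
RCP8.5,intensification,21657.23
RCP8.5,not_recommended,472200.93
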