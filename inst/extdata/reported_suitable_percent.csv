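scenario,period,percent
current,current,19.09
ssp126,2090s,23.24
ssp585,2050s,22.05
ssp585,2090s,20.27
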