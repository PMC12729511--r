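period,scenario,high,moderate,low,total
2050s,ssp126,61.21,62.58,82.88,206.67
2050s,ssp585,67.99,60.47,83.49,211.94
2090s,ssp126,74.57,60.38,88.40,223.35
2090s,ssp585,46.13,69.15,79.50,194.77
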