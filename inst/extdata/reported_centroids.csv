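track,scenario,lon,lat,reported_distance_km
ssp126,present,110.65,27.79,NA
ssp126,2050s,109.31,27.81,132.57
ssp126,2090s,108.90,28.00,45.04
ssp585,present,110.65,27.79,NA
ssp585,2050s,108.23,27.77,238.58
ssp585,2090s,109.49,27.84,124.56
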