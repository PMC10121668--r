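gcm,scenario,year,stable_absence_km2,stable_presence_km2,loss_pct,gain_pct,net_change_pct
GFDL-ESM4,SSP126,2050,111869,18093,34.312,34.458,0.145
GFDL-ESM4,SSP126,2080,112054,19217,30.232,33.786,3.554
GFDL-ESM4,SSP370,2050,111853,14621,41.502,48.240,6.738
GFDL-ESM4,SSP370,2080,117198,8505,65.972,26.854,-39.117
GFDL-ESM4,SSP585,2050,112867,13943,47.329,36.133,-11.197
GFDL-ESM4,SSP585,2080,114267,10053,62.024,30.844,-31.180
MRI-ESM2-0,SSP126,2050,130689,6866,59.130,7.777,-57.355
MRI-ESM2-0,SSP126,2080,131155,7594,54.687,5.907,-48.780
MRI-ESM2-0,SSP370,2050,116164,11850,55.273,23.575,-31.698
MRI-ESM2-0,SSP370,2080,115600,6655,74.881,25.704,-49.177
MRI-ESM2-0,SSP585,2050,115958,16730,38.979,20.166,-18.813
MRI-ESM2-0,SSP585,2080,118306,13903,49.291,11.602,-37.688
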