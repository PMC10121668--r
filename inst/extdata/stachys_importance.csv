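algorithm,Bio1,Bio8,Bio12,Elevation,Bio13,Bio10,Bio5,Bio9,Bio2,Bio7
GLM,22.72,45.29,17.90,8.56,8.02,38.52,5.15,1.26,5.24,0.36
GBM,6.19,24.60,8.76,1.87,2.13,0.04,0.55,0.81,3.01,1.76
RF,3.01,7.04,2.23,1.53,2.12,0.49,0.62,0.61,1.20,1.37
SRE,33.98,25.70,29.26,33.40,28.71,28.90,27.97,29.20,11.07,12.25
CTA,79.42,21.11,3.19,4.02,4.15,3.05,3.84,3.04,4.20,0.35
ANN,12.24,31.66,81.98,44.31,46.18,10.18,17.58,9.59,11.43,10.62
FDA,40.14,45.02,39.30,30.64,17.20,20.05,25.40,13.32,14.00,9.66
MARS,57.42,52.60,41.48,22.85,18.07,14.53,26.48,22.61,10.15,7.76
GAM,65.44,52.20,74.51,65.15,71.66,74.54,64.98,72.32,43.18,50.07
MAXENT,41.10,39.06,37.00,7.08,14.40,0.10,8.52,6.28,16.47,9.90
Relative importance,36.17,34.43,33.56,21.94,21.26,19.04,18.11,15.90,12.00,10.41
Contribution,16.22,15.44,15.05,9.84,9.54,8.54,8.12,7.13,5.38,4.67
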