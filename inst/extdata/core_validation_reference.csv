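# Published core-vs-entire representativeness table for the 318-genotype panel
# and its 64-genotype mini-core: per-trait coincidence rate of range (CR%),
# variable rate (VR%), variance difference (VD%), mean difference (MD%),
# Shannon-Weaver indices (core, entire), and p-values of the Newman-Keuls,
# Levene and Wilcoxon rank-sum comparisons.
trait,CR,VR,VD,MD,H_core,H_entire,p_newman_keuls,p_levene,p_wilcoxon
RGR,99.97,175.87,43.14,8.69,3.97,5.63,0.22,0.03,0.59
RNIL,91.18,128.54,22.20,3.57,4.09,5.70,0.43,0.22,0.43
RLER,94.08,137.70,27.38,2.38,4.10,5.72,0.54,0.08,0.62
SWC,92.25,132.98,24.80,4.48,4.10,5.72,0.30,0.20,0.24
RWC,79.34,101.32,1.30,5.60,4.10,5.71,0.23,0.79,0.22
Sen,100.00,131.25,23.81,0.18,4.14,5.75,0.94,0.42,0.90
SNC,100.00,142.09,29.62,0.30,4.13,5.74,0.92,0.21,0.88
RNC,79.75,121.40,17.63,0.45,4.13,5.73,0.89,0.15,0.94
SN/RN,99.58,157.12,36.35,0.64,4.11,5.73,0.85,0.03,0.57
SKC,94.49,145.92,31.47,1.86,4.15,5.76,0.25,0.12,0.40
RKC,94.93,137.77,27.41,0.56,4.13,5.74,0.85,0.07,0.83
SK/RK,96.39,146.88,31.92,3.29,4.11,5.73,0.39,0.12,0.71
SK/N,97.92,172.77,42.12,4.64,4.11,5.73,0.19,0.09,0.64
RK/N,100.00,144.69,30.89,0.77,4.10,5.72,0.86,0.05,0.86
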