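# Published seven-predictor seedling salt-tolerance regression (unstandardized B,
# standard error, standardized beta, t, p); reported model R^2 = 0.962.
term,B,se,beta,t,p
(Constant),0.6895,0.0108,,63.58,0.00
SNC,-0.0012,0.0000,-0.4140,-25.48,0.00
RNIL,0.1242,0.0062,0.2689,20.17,0.00
RWC,0.0057,0.0002,0.2912,23.82,0.00
RGR,0.0516,0.0033,0.1884,15.63,0.00
RKC,-0.0023,0.0002,-0.1793,-14.90,0.00
Sen,-0.0202,0.0013,-0.2791,-16.06,0.00
RNC,-0.0010,0.0001,-0.1601,-12.39,0.00
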