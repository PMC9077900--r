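gene_symbol,target_family,screened,positives,hit_percent_printed
ADORA3,GPCR,2834,832,29.35
DRD2,GPCR,2606,346,13.27
OPRM1,GPCR,2573,364,14.14
CHRM1,GPCR,2533,916,36.16
HTR2A,GPCR,2391,526,21.99
ADORA1,GPCR,2378,102,4.28
SLC6A2,Transporters,2360,393,16.65
5-HT2B,GPCR,2316,823,35.53
DRD1,GPCR,2301,241,10.47
HTR1A,GPCR,2290,290,12.66
HRH1,GPCR,2286,214,9.36
CHRM2,GPCR,2253,513,22.76
ADRB1,GPCR,2252,60,2.66
ACHE,Other-enzymes,2245,418,18.61
SLC6A4,Transporters,2241,799,35.65
GABRA1(CL-),Ion-channel,2238,448,20.01
ADRA1A,GPCR,2210,380,17.19
MAOA,Other-enzymes,2204,20,0.90
5-HT3,Ion-channel,2130,50,2.34
HIV1-PR,Other-enzymes,2110,46,2.18
ADRA2A,GPCR,2020,196,9.70
ADRB2,GPCR,1973,76,3.85
PPARG,Nuclear-receptor,1955,194,9.92
CACNA1C,Ion-channel,1942,473,24.35
CHRNA1,Ion-channel,1899,173,9.11
PTGFR,GPCR,1897,73,3.84
HRH3,GPCR,1864,215,11.53
XDH,Other-enzymes,1831,49,2.67
NR3C1,Nuclear-receptor,1816,76,4.18
PTGS2,Other-enzymes,1799,192,10.67
CCKAR,GPCR,1792,139,7.75
MMP9,Other-enzymes,1787,38,2.12
AGTR1,GPCR,1762,45,2.55
GABRA1(Benzo),Ion-channel,1645,329,20
HRH2,GPCR,1644,123,7.48
CNR1,GPCR,1609,67,4.16
PDE3B,Other-enzymes,1563,66,4.22
ZAP70,Kinases,1484,25,1.68
CDK2,Kinases,1465,61,4.16
GSK3B,Kinases,1394,65,4.66
ESR1,Nuclear-receptor,1389,7,0.50
ABL1,Kinases,1328,236,17.77
GSK3A,Kinases,1285,97,7.54
AR,Nuclear-receptor,1234,86,6.96
PCP,Ion-channel,1187,6,0.50
Glycine,Ion-channel,1145,2,0.17
CHRNA4,Ion-channel,951,9,0.94
ACE2,Other-enzymes,832,58,6.97
OPRK1,GPCR,428,89,20.79
PDE4D2,Other-enzymes,133,15,11.27
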