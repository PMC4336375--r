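system,water_id,E_sw,E_ww,dE_ifst,mTS_sw,mTS_ww,mTdS_ifst,dG_ifst
IL-1beta,202,-15.93,-2.69,-7.05,6.35,0.07,1.80,-5.25
IL-1beta,204,-16.73,-2.72,-7.88,6.41,0.07,1.86,-6.02
IL-1beta,203,-14.56,-1.97,-4.96,6.63,0.10,2.11,-2.85
IL-1beta,207,-13.75,-1.99,-4.16,5.77,0.10,1.25,-2.91
IL-1beta,200,-21.21,NA,-9.48,6.53,NA,1.91,-7.57
IL-1beta,209,-19.04,NA,-7.33,5.08,NA,0.46,-6.87
T4-lysozyme,902,-22.13,-2.95,-13.50,6.72,0.05,2.16,-11.34
T4-lysozyme,905,-18.67,-2.97,-10.06,6.45,0.05,1.88,-8.18
T4-lysozyme,904,-16.23,NA,-4.65,6.27,NA,1.65,-3.00
T4-lysozyme,920,-21.10,NA,-9.54,6.40,NA,1.78,-7.76
FKBP-2,207,-17.96,-2.37,-8.76,6.01,0.08,1.48,-7.29
FKBP-2,208,-19.54,-2.44,-10.40,6.09,0.08,1.56,-8.85
FKBP-2,203,-26.49,NA,-14.91,7.03,NA,2.41,-12.50
CA-II,2004,-20.77,NA,-9.47,6.47,NA,1.85,-7.62
CA-II,2015,-27.52,NA,-15.92,6.85,NA,2.23,-13.70
CA-II,2031,-22.40,NA,-11.09,6.28,NA,1.66,-9.44
CA-II,2042,-24.11,NA,-12.56,6.59,NA,1.97,-10.58
CA-II,2055,-17.80,NA,-6.20,6.66,NA,2.04,-4.17
beta-lactamase,2023,-16.08,NA,-3.95,6.02,NA,1.40,-2.55
beta-lactamase,2048,-27.94,NA,-16.33,7.09,NA,2.47,-13.87
beta-lactamase,2073,-28.60,NA,-16.47,6.52,NA,1.90,-14.57
beta-lactamase,2105,-24.70,NA,-13.08,5.93,NA,1.31,-11.77
beta-lactamase,2327,-30.27,NA,-18.70,7.29,NA,2.67,-16.03
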