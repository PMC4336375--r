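system,site_id,dG_reference,dG_ifst
IL-1beta,W202+W204,-11.77,-11.27
IL-1beta,W203+W207,-6.18,-5.76
IL-1beta,W200,-7.09,-7.57
IL-1beta,W209,-6.90,-6.87
T4-lysozyme,W902+W905,-20.41,-19.52
T4-lysozyme,W904,-3.33,-3.00
T4-lysozyme,W920,-8.29,-7.76
FKBP-2,W207+W208,-16.70,-16.13
FKBP-2,W203,-13.07,-12.50
CA-II,W2004,-8.21,-7.62
CA-II,W2015,-14.05,-13.70
CA-II,W2031,-10.06,-9.44
CA-II,W2042,-11.09,-10.58
CA-II,W2055,-4.29,-4.17
beta-lactamase,W2023,-2.31,-2.55
beta-lactamase,W2048,-14.30,-13.87
beta-lactamase,W2073,-13.98,-14.57
beta-lactamase,W2105,-12.06,-11.77
beta-lactamase,W2327,-16.53,-16.03
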