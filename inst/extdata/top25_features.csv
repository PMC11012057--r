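feature,vip,rt,formula,adduct,mz,error_ppm,fragments,identification
M1,3.14,37.028,C14H14O2,[M+H]+,215.10686,0.950,197.09605 171.08034 169.06474 153.06985 126.06200 115.05412 107.04900 91.05415 77.03855,Not identified
M2,2.36,8.911,C11H16O3,[M+H]+,197.11722,-0.001,179.10651 161.09559 135.11668 133.10103 107.08538 105.06976 95.04897 91.05408 81.06990 67.05418,Loliolide
M3,2.15,42.581,C28H42N4O5,[M+H]+,515.32123,-3.038,453.16962 317.17847 261.22092 184.07304 135.11687 121.10077 107.08530 81.06983 67.05418,Not identified
M4,2.07,13.201,C21H18O12,[M+H]+,463.08682,-0.608,287.05487 269.04379 241.04924 229.03900 213.05444 203.03415 179.03360 171.02832 161.02264 153.01826 137.02319 135.04413 117.03323 115.05326 89.03847,Luteolin-7-O-b-D-glucuronide
M5,2.57,47.401,C27H50N2O4,[M+Na]+,467.38544,-1.093,256.01831 229.02219 142.03166 90.43191 64.22938,Not identified
M6,2.02,32.150,C46H50N4O8,[M+H]+,787.36951,-0.799,641.33398 623.32062 495.29810 477.28815 250.25378 275.17529 203.11819 147.04408 129.13860 119.04903 112.11247 91.05423,Tetra-trans-p-coumaroylspermine isomer
M7,2.39,20.884,C24H22O13,[M+H]+,519.11322,-0.185,299.06247 271.06012 229.02782 153.01810 119.04888 91.05378 68.99718 67.01790,Apigenin-7-O-malonylglucoside isomer
M8,7.22,24.417,C24H22O13,[M+H]+,519.11310,-0.417,271.05997 243.06416 229.05414 171.02888 163.03972 153.01813 145.02803 119.04910 91.05403 68.99709 67.01784,Apigenin-7-O-malonylglucoside
M9,3.09,17.164,C21H20O10,[M+Na]+,455.09405,-1.796,329.05490 293.04218 229.03677 203.08504 71.06578 68.14845,Apigenin-7-O-b-D-glucoside (M10)
M10,11.34,17.197,C21H20O10,[M+H]+,433.11258,-0.791,271.06003 243.06487 229.04843 203.08511 171.02910 163.03928 153.01814 145.02826 119.04900 91.05417 68.99722 67.01775,Apigenin-7-O-b-D-glucoside
M11,2.82,17.198,C15H10O5,[M+H]+,271.06009,-0.035,229.01183 203.08510 171.02907 163.03899 153.01833 145.02829 119.04906 91.05415 68.99709,Apigenin-7-O-b-D-glucoside (ISF product of M10)
M12,4.35,19.155,C22H22O11,[M+H]+,463.12317,-0.685,301.07019 286.04672 258.05182 229.04846 153.01793 106.04081 59.89636,Diosmetin-7-O-b-D-glucoside isomer
M13,3.27,25.323,C25H24O14,[M+H]+,549.12366,-0.402,463.12891 301.07059 286.04712 258.05209 229.04926 153.01816 68.99689,Diosmetin-7-O-(6''-malonylglucoside) isomer
M14,2.82,15.098,C9H6O3,[M+H]+,163.03903,0.367,149.06023 145.03960 117.03344 107.04896 95.04910 89.03857 79.05422,"1,5-O-Dicaffeoyl quinic acid (ISF product of M15)"
M15,2.32,15.099,C25H24O12,[M+H]+,517.13367,-0.738,337.09283 319.08026 229.03595 163.03897 145.02834 135.04405 117.03335 107.04913 95.04906 89.03851,"1,5-O-Dicaffeoyl quinic acid"
M16,2.01,15.100,C16H18O9,[M+H]+,355.10239,0.091,229.03082 203.08519 163.03896 145.02837 117.03336 89.03949,"1,5-O-Dicaffeoyl quinic acid (ISF product of M15)"
M17,4.28,22.809,C15H24O3,[M+Na]+,275.16187,0.381,229.01579 175.07280 165.59151 73.07964 60.67187 57.18082,Indicumenone
M18,3.50,36.799,C15H26O2,[M+Na]+,261.18246,-0.156,229.02008 141.96776 118.73338 93.66092 83.32710,Drimendiol
M19,2.48,28.268,C15H24O3,[M+Na]+,275.16180,0.126,229.04546 203.08495 194.26845 160.05701 114.43626 103.98212 70.73609 65.73772,Ilicic acid
M20,2.56,35.532,C15H24O2,[M-H2O+H]+,219.17448,-1.869,201.16397 173.13269 163.11157 145.10121 135.08055 119.08559 107.08549 95.08551 93.06987 81.06995 67.05430,a-Cyperone
M21,2.03,19.411,C19H26O7,[M+Na]+,389.15700,-0.189,367.98987 302.21576 247.13544 229.01994 203.08496 173.09686 145.10120 131.08569 91.05424,Not identified
M22,4.01,32.815,C19H26O6,[M+Na]+,373.16,2.066,313.14053 271.13022 253.11945 231.13818 157.10114 142.07777 129.07016 105.07031 83.01060,"1,6-O,O-Diacetylbritannilactone"
M23,3.62,29.930,C15H10O5,[M+H]+,271.05945,-2.396,243.006442 229.04283 225.05389 171.02852 153.01788 145.02776 121.02822 119.04874 91.05399 68.99594 67.01771,Apigenin
M24,2.22,30.496,C16H12O6,[M+H]+,301.07037,-0.977,286.04688 258.05194 229.04887 153.01804 106.04115 58.59438 54.55778,Diosmetin
M25,4.30,34.924,C16H12O5,[M+H]+,285.07574,-0.033,270.05237 242.05739 153.01828 133.06473 124.01496 118.04072 90.04630 68.99710 67.01776,Acacetin
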