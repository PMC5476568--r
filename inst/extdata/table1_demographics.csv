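arm,variable,type,g1_mean,g1_sd,g1_n,g2_mean,g2_sd,g2_n,g1_x,g1_y,g2_x,g2_y
bvftd,sex,categorical,NA,NA,13,NA,NA,25,7,6,15,10
bvftd,age,continuous,69.31,10.55,13,70.40,5.22,25,NA,NA,NA,NA
bvftd,education,continuous,15,3.34,13,16.96,3.47,25,NA,NA,NA,NA
bvftd,ace_total,continuous,70.77,10.66,13,92.17,6.84,25,NA,NA,NA,NA
bvftd,ravlt_immediate,continuous,24.23,8.87,13,42.89,10.07,25,NA,NA,NA,NA
bvftd,ravlt_delayed,continuous,3.69,2.81,13,7.28,3.32,25,NA,NA,NA,NA
bvftd,ifs_total,continuous,15.65,4.39,13,24.94,2.25,25,NA,NA,NA,NA
ad,sex,categorical,NA,NA,13,NA,NA,18,11,2,12,6
ad,age,continuous,75.62,9.42,13,72.28,4.42,18,NA,NA,NA,NA
ad,education,continuous,12.77,7.60,13,15.94,3.35,18,NA,NA,NA,NA
ad,ace_total,continuous,78.62,11.86,13,93.12,6.06,18,NA,NA,NA,NA
ad,ravlt_immediate,continuous,27.46,8.25,13,42.68,10.19,18,NA,NA,NA,NA
ad,ravlt_delayed,continuous,1.31,3.12,13,7.11,3.38,18,NA,NA,NA,NA
ad,ifs_total,continuous,17.77,7.57,13,25.40,2.26,18,NA,NA,NA,NA
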