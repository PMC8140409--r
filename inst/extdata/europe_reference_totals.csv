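# Published regional attributable-mortality totals for Europe, present period
# (thousands of deaths per year; low/high are the printed 95% CI bounds).
# Used as fixtures for report arithmetic (aggregation, shares, percent change).
region,endpoint,central,low,high
Western,CEV,8,6.3,8.7
Western,IHD,41,34.1,46.8
Western,COPD,9,7,10
Western,LC,13,11,15.2
Western,LRI,11,9.5,13.1
Western,OTHER_NCD,84,44.5,123.8
Western,NCD_LRI,166,134,195.4
Central,CEV,23,19.1,26.2
Central,IHD,100,83.7,114.8
Central,COPD,9,7.1,9.9
Central,LC,15,12.7,17.5
Central,LRI,10,8.7,12.1
Central,OTHER_NCD,84,44.2,123
Central,NCD_LRI,241,194.7,283.7
Eastern,CEV,59,49.1,67.3
Eastern,IHD,294,247.2,338.6
Eastern,COPD,11,9,12.3
Eastern,LC,18,15,20.9
Eastern,LRI,20,16.9,23.3
Eastern,OTHER_NCD,95,50,139
Eastern,NCD_LRI,497,401.9,585.7
EUROPE,CEV,90,75.5,103.5
EUROPE,IHD,435,365.4,500.3
EUROPE,COPD,29,24.3,33.4
EUROPE,LC,46,38.5,52.9
EUROPE,LRI,41,34.3,47.2
EUROPE,OTHER_NCD,263,144.6,386.6
EUROPE,NCD_LRI,904,733.1,1067.8
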