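# Published age-resolved attributable-mortality totals for Europe (thousands of
# deaths per year, central estimates), present and future scenario, with the
# printed TOTAL rows. Fixture for report-arithmetic consistency checks.
endpoint,period,age_group,central
CEV,present,25-29,0
CEV,present,30-34,1
CEV,present,35-39,1
CEV,present,40-44,1
CEV,present,45-49,2
CEV,present,50-54,4
CEV,present,55-59,5
CEV,present,60-64,8
CEV,present,65-69,8
CEV,present,70-74,12
CEV,present,75-79,15
CEV,present,80plus,33
CEV,present,TOTAL,90
CEV,future,25-29,0
CEV,future,30-34,0
CEV,future,35-39,1
CEV,future,40-44,1
CEV,future,45-49,2
CEV,future,50-54,3
CEV,future,55-59,5
CEV,future,60-64,11
CEV,future,65-69,14
CEV,future,70-74,18
CEV,future,75-79,21
CEV,future,80plus,78
CEV,future,TOTAL,154
IHD,present,25-29,1
IHD,present,30-34,2
IHD,present,35-39,4
IHD,present,40-44,6
IHD,present,45-49,13
IHD,present,50-54,21
IHD,present,55-59,30
IHD,present,60-64,42
IHD,present,65-69,41
IHD,present,70-74,59
IHD,present,75-79,62
IHD,present,80plus,154
IHD,present,TOTAL,435
IHD,future,25-29,1
IHD,future,30-34,2
IHD,future,35-39,3
IHD,future,40-44,6
IHD,future,45-49,9
IHD,future,50-54,15
IHD,future,55-59,29
IHD,future,60-64,56
IHD,future,65-69,67
IHD,future,70-74,82
IHD,future,75-79,104
IHD,future,80plus,372
IHD,future,TOTAL,746
COPD,present,25-29,0
COPD,present,30-34,0
COPD,present,35-39,0
COPD,present,40-44,0
COPD,present,45-49,0
COPD,present,50-54,1
COPD,present,55-59,1
COPD,present,60-64,2
COPD,present,65-69,3
COPD,present,70-74,4
COPD,present,75-79,4
COPD,present,80plus,14
COPD,present,TOTAL,29
COPD,future,25-29,0
COPD,future,30-34,0
COPD,future,35-39,0
COPD,future,40-44,0
COPD,future,45-49,0
COPD,future,50-54,1
COPD,future,55-59,1
COPD,future,60-64,3
COPD,future,65-69,4
COPD,future,70-74,6
COPD,future,75-79,7
COPD,future,80plus,31
COPD,future,TOTAL,53
LC,present,25-29,0
LC,present,30-34,0
LC,present,35-39,0
LC,present,40-44,1
LC,present,45-49,2
LC,present,50-54,3
LC,present,55-59,5
LC,present,60-64,8
LC,present,65-69,7
LC,present,70-74,8
LC,present,75-79,5
LC,present,80plus,7
LC,present,TOTAL,46
LC,future,25-29,0
LC,future,30-34,0
LC,future,35-39,0
LC,future,40-44,1
LC,future,45-49,1
LC,future,50-54,3
LC,future,55-59,6
LC,future,60-64,10
LC,future,65-69,11
LC,future,70-74,11
LC,future,75-79,10
LC,future,80plus,17
LC,future,TOTAL,70
LRI,present,25-29,0
LRI,present,30-34,1
LRI,present,35-39,2
LRI,present,40-44,2
LRI,present,45-49,2
LRI,present,50-54,2
LRI,present,55-59,3
LRI,present,60-64,3
LRI,present,65-69,3
LRI,present,70-74,3
LRI,present,75-79,4
LRI,present,80plus,16
LRI,present,TOTAL,41
LRI,future,25-29,0
LRI,future,30-34,1
LRI,future,35-39,1
LRI,future,40-44,2
LRI,future,45-49,2
LRI,future,50-54,2
LRI,future,55-59,3
LRI,future,60-64,4
LRI,future,65-69,4
LRI,future,70-74,5
LRI,future,75-79,6
LRI,future,80plus,42
LRI,future,TOTAL,72
NCD_LRI,present,25-29,5
NCD_LRI,present,30-34,8
NCD_LRI,present,35-39,13
NCD_LRI,present,40-44,18
NCD_LRI,present,45-49,28
NCD_LRI,present,50-54,44
NCD_LRI,present,55-59,62
NCD_LRI,present,60-64,81
NCD_LRI,present,65-69,82
NCD_LRI,present,70-74,113
NCD_LRI,present,75-79,118
NCD_LRI,present,80plus,332
NCD_LRI,present,TOTAL,904
NCD_LRI,future,25-29,4
NCD_LRI,future,30-34,6
NCD_LRI,future,35-39,11
NCD_LRI,future,40-44,16
NCD_LRI,future,45-49,22
NCD_LRI,future,50-54,35
NCD_LRI,future,55-59,59
NCD_LRI,future,60-64,105
NCD_LRI,future,65-69,130
NCD_LRI,future,70-74,156
NCD_LRI,future,75-79,198
NCD_LRI,future,80plus,818
NCD_LRI,future,TOTAL,1560
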