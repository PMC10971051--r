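study_id,arm,endpoint,timepoint_months,measure,subgroup,n,mean,sd,source
osia1,osia,age,0,baseline,all,51,47.4,14.7,enrolled cohort demographics
osia2,osia,age,0,baseline,all,29,46.7,19.7,enrolled cohort demographics
baha1,baha,age,0,baseline,all,54,42.1,13.6,enrolled cohort demographics
osia1,osia,pta4,0,baseline,all,51,53.90,11.60,patient-level data extract
osia2,osia,pta4,0,baseline,all,29,53.60,11.30,patient-level data extract
baha1,baha,pta4,0,baseline,all,54,51.94,10.46,first-principles pooling of CHL/MHL and SSD subgroups
osia1,osia,pta4,6,change,all,49,27.90,9.10,patient-level data extract
osia2,osia,pta4,6,change,all,28,28.40,9.60,patient-level data extract
baha1,baha,pta4,6,change,all,54,21.02,10.41,first-principles pooling of CHL/MHL and SSD subgroups
osia1,osia,speech_quiet,0,baseline,all,51,25.50,25.40,patient-level data extract
osia2,osia,speech_quiet,0,baseline,all,29,37.80,30.30,patient-level data extract
baha1,baha,speech_quiet,0,baseline,all,54,46.76,32.62,first-principles pooling of CHL/MHL and SSD subgroups
osia1,osia,speech_quiet,6,change,all,48,61.50,27.70,patient-level data extract
osia2,osia,speech_quiet,6,change,all,28,54.00,29.80,patient-level data extract
baha1,baha,speech_quiet,6,change,all,54,43.44,31.47,first-principles pooling of CHL/MHL and SSD subgroups
osia1,osia,speech_noise,0,baseline,all,51,4.98,7.76,patient-level data extract; noise from behind
baha1,baha,speech_noise,0,baseline,all,36,8.57,6.26,first-principles pooling; noise from behind
osia1,osia,speech_noise,6,change,all,48,13.70,8.10,patient-level data extract; noise from behind
baha1,baha,speech_noise,6,change,all,36,4.26,5.66,first-principles pooling; noise from behind
osia1,osia,hui3,0,baseline,all,46,0.65,0.22,patient-level data extract
osia2,osia,hui3,0,baseline,all,29,0.69,0.23,patient-level data extract
baha1,baha,hui3,0,baseline,all,52,0.66,0.24,published summary
osia1,osia,hui3,3,change,all,42,0.08,0.23,patient-level data extract
osia2,osia,hui3,3,change,all,27,0.10,0.17,patient-level data extract
osia2,osia,hui3,6,change,all,27,0.09,0.17,patient-level data extract; 12-month-reporting study excluded at 6 months
baha1,baha,hui3,6,change,all,47,0.06,0.25,published summary
osia1,osia,hui3,0,baseline,chl_mhl,34,0.61,0.22,patient-level data extract
osia2,osia,hui3,0,baseline,chl_mhl,24,0.65,0.22,patient-level data extract
baha1,baha,hui3,0,baseline,chl_mhl,37,0.67,0.21,published summary
osia1,osia,hui3,3,change,chl_mhl,30,0.10,0.24,patient-level data extract
osia2,osia,hui3,3,change,chl_mhl,23,0.12,0.17,patient-level data extract
osia2,osia,hui3,6,change,chl_mhl,23,0.12,0.15,patient-level data extract
baha1,baha,hui3,6,change,chl_mhl,34,0.06,0.23,published summary
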