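ptt,date_deployment,tag_duration_days,sex,min_total_distance_km,social_category,mean_speed_kmh,breeding_speed_kmh,migratory_speed_kmh,pct_ars,pct_transit,pct_uncertain
24638-07,2007-08-19,26,F,1860,MCE,2.9,2.7,NA,25.0,25.0,50.0
24639-07,2007-09-01,39,M,2942,CG+MC,3.2,2.2,4.3,54.9,29.6,15.5
24641-07,2007-08-27,13.5,M,769,CG,2.5,2.5,NA,74.1,0.0,26.0
24642-07,2007-09-10,18.5,F,938,P,2.2,1.9,NA,8.1,5.4,86.5
26712-07,2007-08-27,21.5,M,1533,S,3.0,2.0,3.8,65.1,20.9,14.0
27258-07,2007-09-02,8,M,270,CG,1.5,1.5,NA,37.5,0.0,62.5
27259-07,2007-09-09,52.5,F,3340,MC,2.7,2.5,2.7,47.0,46.1,6.9
33000-07,2007-09-02,7.5,M,608,CG,3.7,3.7,NA,92.9,0.0,7.1
33001-07,2007-09-07,14.5,M,1132,P,3.6,NA,3.6,7.4,0.0,92.6
37229-07,2007-09-10,22,F,2131,P,4.2,NA,4.3,0.0,95.3,4.7
37230-07,2007-09-11,43.5,F,2114,MC,2.0,2.0,NA,77.4,0.0,22.6
81122-10,2010-08-07,24.5,M,820,P,1.4,1.4,NA,87.5,0.0,12.5
81123-10,2010-08-08,36.5,F,2524,MCE,3.1,1.9,4.0,1.5,34.3,64.2
84480-10,2010-08-15,16,F,1379,CG,3.8,NA,4.1,0.0,80.0,20.0
84482-10,2010-08-15,19,M,1736,S,3.9,NA,4.5,0.0,97.4,2.6
84484-10,2010-08-15,20.5,M,467,MC+MC,1.1,1.1,NA,86.5,0.0,13.5
84485-10,2010-08-27,17.5,M,1173,P,2.9,2.5,3.5,70.6,0.0,29.4
84486-10,2010-08-15,18.5,M,649,CG+MC,1.5,1.5,NA,8.6,2.9,88.5
84487-10,2010-08-16,51.5,M,4738,P,3.9,NA,4.1,0.0,100.0,0.0
84488-10,2010-08-17,19,M,2050,P,4.7,NA,4.9,0.0,97.3,2.7
87774-10,2010-08-02,35.5,M,1247,2-3,1.5,1.5,NA,97.1,0.0,2.9
87775-10,2010-08-03,16.5,F,584,P,1.6,1.6,NA,93.8,0.0,6.2
81122-11,2011-09-17,20,F,1733,CG,3.7,NA,3.8,0.0,85.0,15.0
81123-11,2011-08-29,17,F,1092,MC,2.9,1.9,4.2,0.0,90.6,9.4
81126-11,2011-09-08,54.5,F,3397,S,2.6,NA,2.6,0.9,64.5,34.6
84485-11,2011-08-31,48,F,2573,MC,2.3,NA,2.3,0.0,98.9,1.1
84487-11,2011-08-25,16,M,1097,P,3.0,1.9,4.0,13.3,10.0,76.7
84494-11,2011-09-01,15.5,F,929,MC,2.9,2.9,NA,96.1,0.0,3.9
87631-11,2011-08-27,11.5,M,1163,P,4.4,2.9,NA,4.4,39.1,56.5
87638-11,2011-08-29,23.5,F,1001,MC,1.8,1.8,NA,28.3,0.0,71.7
87759-11,2011-08-30,21.5,M,2358,P,4.5,NA,4.6,5.0,27.5,67.5
87760-11,2011-08-31,31,F,1583,MC,2.2,2.2,NA,23.7,5.1,71.2
87762-11,2011-09-16,9,M,264,E,1.3,1.3,NA,94.4,0.0,5.6
87761-12,2012-09-28,110,F,8540,MC,3.2,2.3,3.3,4.1,86.7,9.2
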