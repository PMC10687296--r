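disease,panel,group,year,prevalence,source
Asthma,region,overall,2013,3.7,table2
Chronic lung diseases,region,overall,2013,4.7,table2
Myocardial infarction,region,overall,2013,2.8,table2
Coronary heart disease,region,overall,2013,11.6,table2
Hypertension,region,overall,2013,34.0,table2
Stroke,region,overall,2013,2.2,table2
Arthrosis,region,overall,2013,10.4,table2
Lower back diseases,region,overall,2013,20.5,table2
Cervical spine diseases,region,overall,2013,13.2,table2
Diabetes mellitus,region,overall,2013,8.4,table2
Allergies,region,overall,2013,8.8,table2
Liver cirrhosis,region,overall,2013,0.3,table2
Urinary track diseases,region,overall,2013,4.6,table2
Kidney diseases,region,overall,2013,6.1,table2
Depression,region,overall,2013,6.7,table2
High Cholesterol,region,overall,2013,13.9,table2
Cancer,region,overall,2013,1.6,table2
Asthma,region,overall,2019,3.6,table2
Chronic lung diseases,region,overall,2019,3.7,table2
Myocardial infarction,region,overall,2019,2.0,table2
Coronary heart disease,region,overall,2019,9.8,table2
Hypertension,region,overall,2019,32.3,table2
Stroke,region,overall,2019,1.4,table2
Arthrosis,region,overall,2019,7.8,table2
Lower back diseases,region,overall,2019,18.4,table2
Cervical spine diseases,region,overall,2019,13.0,table2
Diabetes mellitus,region,overall,2019,8.8,table2
Allergies,region,overall,2019,7.0,table2
Liver cirrhosis,region,overall,2019,0.3,table2
Urinary track diseases,region,overall,2019,3.9,table2
Kidney diseases,region,overall,2019,4.2,table2
Depression,region,overall,2019,4.8,table2
High Cholesterol,region,overall,2019,11.2,table2
Cancer,region,overall,2019,2.0,table2
Asthma,age,overall,2013,3.6,table3
Chronic lung diseases,age,overall,2013,4.7,table3
Myocardial infarction,age,overall,2013,2.7,table3
Coronary heart disease,age,overall,2013,11.6,table3
Hypertension,age,overall,2013,34.1,table3
Stroke,age,overall,2013,2.3,table3
Arthrosis,age,overall,2013,10.5,table3
Lower back diseases,age,overall,2013,20.5,table3
Cervical spine diseases,age,overall,2013,13.2,table3
Diabetes mellitus,age,overall,2013,8.6,table3
Allergies,age,overall,2013,8.8,table3
Liver cirrhosis,age,overall,2013,0.2,table3
Urinary track diseases,age,overall,2013,4.5,table3
Kidney diseases,age,overall,2013,6.1,table3
Depression,age,overall,2013,6.8,table3
High Cholesterol,age,overall,2013,13.9,table3
Cancer,age,overall,2013,1.5,table3
Asthma,age,overall,2019,3.6,table3
Chronic lung diseases,age,overall,2019,3.7,table3
Myocardial infarction,age,overall,2019,2.0,table3
Coronary heart disease,age,overall,2019,9.7,table3
Hypertension,age,overall,2019,32.4,table3
Stroke,age,overall,2019,1.5,table3
Arthrosis,age,overall,2019,7.7,table3
Lower back diseases,age,overall,2019,18.5,table3
Cervical spine diseases,age,overall,2019,13.1,table3
Diabetes mellitus,age,overall,2019,8.6,table3
Allergies,age,overall,2019,7.0,table3
Liver cirrhosis,age,overall,2019,0.3,table3
Urinary track diseases,age,overall,2019,3.8,table3
Kidney diseases,age,overall,2019,4.2,table3
Depression,age,overall,2019,4.7,table3
High Cholesterol,age,overall,2019,11.4,table3
Cancer,age,overall,2019,2.0,table3
Asthma,gender,male,NA,1.7,table4
Chronic lung diseases,gender,male,NA,1.8,table4
Myocardial infarction,gender,male,NA,1.5,table4
Coronary heart disease,gender,male,NA,4.3,table4
Hypertension,gender,male,NA,13.9,table4
Stroke,gender,male,NA,0.9,table4
Arthrosis,gender,male,NA,2.6,table4
Lower back diseases,gender,male,NA,7.3,table4
Cervical spine diseases,gender,male,NA,4.1,table4
Diabetes mellitus,gender,male,NA,3.9,table4
Allergies,gender,male,NA,2.8,table4
Liver cirrhosis,gender,male,NA,0.2,table4
Urinary track diseases,gender,male,NA,2.1,table4
Kidney diseases,gender,male,NA,2.0,table4
Depression,gender,male,NA,1.9,table4
High Cholesterol,gender,male,NA,4.8,table4
Cancer,gender,male,NA,0.6,table4
Asthma,gender,female,NA,2.1,table4
Chronic lung diseases,gender,female,NA,2.4,table4
Myocardial infarction,gender,female,NA,0.9,table4
Coronary heart disease,gender,female,NA,6.4,table4
Hypertension,gender,female,NA,19.3,table4
Stroke,gender,female,NA,0.9,table4
Arthrosis,gender,female,NA,6.5,table4
Lower back diseases,gender,female,NA,12.2,table4
Cervical spine diseases,gender,female,NA,9.0,table4
Diabetes mellitus,gender,female,NA,4.7,table4
Allergies,gender,female,NA,5.2,table4
Liver cirrhosis,gender,female,NA,0.2,table4
Urinary track diseases,gender,female,NA,2.2,table4
Kidney diseases,gender,female,NA,3.1,table4
Depression,gender,female,NA,3.8,table4
High Cholesterol,gender,female,NA,7.9,table4
Cancer,gender,female,NA,1.1,table4
Hypertension,prose,overall,2013,34.0,section4
Hypertension,prose,overall,2019,33.2,section4
Hypertension,prose,overall,2019,32.2,abstract
Lower back diseases,prose,overall,2013,20.4,section4
Lower back diseases,prose,overall,2019,19.5,section4
Cervical spine diseases,prose,overall,2013,13.1,section4
Cervical spine diseases,prose,overall,2019,13.1,section4
High Cholesterol,prose,overall,2013,13.9,section4
High Cholesterol,prose,overall,2019,12.6,section4
Coronary heart disease,prose,overall,2013,11.5,section4
Coronary heart disease,prose,overall,2019,10.7,section4
Arthrosis,prose,overall,2013,10.4,section4
Arthrosis,prose,overall,2019,9.1,section4
Diabetes mellitus,prose,overall,2013,8.4,section4
Diabetes mellitus,prose,overall,2019,8.5,section4
Allergies,prose,overall,2013,8.8,section4
Allergies,prose,overall,2019,8.0,section4
Depression,prose,overall,2013,6.8,section4
Depression,prose,overall,2019,5.8,section4
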