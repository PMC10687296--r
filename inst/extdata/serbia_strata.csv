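margin,level,count
year,2013,14623
year,2019,13178
gender,male,13190
gender,female,14611
region,Belgrade,6760
region,Vojvodina,5925
region,Sumadija-West,8659
region,East-South,6457
age_group,15-24,3241
age_group,25-34,3590
age_group,35-44,4140
age_group,45-54,4317
age_group,55-64,5268
age_group,65-74,4252
age_group,75-84,2510
age_group,85+,483
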