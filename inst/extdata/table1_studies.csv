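study_id,source,location,baseline_years,age_range,pct_male,followup_years,total,cases,mets_definition
andre_2007,DESIR,France,1994-1996,30-65,46.7,3,3545,309,IDF
schindhelm_2007,Hoorn,Netherlands,1989,50-75,42.4,6,1097,226,NCEP-ATP III
jo_2009,HPC,Korea,2002,19-86,70.8,4,21535,802,IDF
nakanishi_2004,Office Workers,Japan,1994,35-59,100,7,2957,608,NCEP-ATP III
xu_2011,City of Shanghai,China,2004-2008,40+,60.2,4,681,180,modified NCEP-ATP III
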