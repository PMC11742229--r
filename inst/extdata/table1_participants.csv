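participant,age_years,sex,years_since_stroke,stroke_type,dominant_side,affected_side,fma_ue_baseline_median,total_training_h,total_training_min,training_per_session_min,n_training_sessions,repetitions_per_session,total_repetitions
P1,64,male,3.5,hemorrhage,left,left,15,17,1045,55,19,88,1584
P2,49,female,1.5,ischemic,right,right,44,24,1463,77,19,123,2337
P3,56,male,1.1,hemorrhage,right,left,13,20,1224,68,18,109,1962
P4,61,male,1.3,ischemic,right,right,14,18,1099,61,18,98,1764
P5,64,male,4.0,hemorrhage,right,left,35,23,1404,78,18,125,2250
P6,40,female,2.6,hemorrhage,right,right,50,23,1386,77,18,123,2214
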