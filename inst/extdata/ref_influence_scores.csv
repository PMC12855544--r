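block,input,target,healthy_coeff,healthy_pos,healthy_neg,t2dm_coeff,t2dm_pos,t2dm_neg,difference,absolute
diet_to_psych,white_bread,fed_up_feelings,-0.33,32,68,0.69,90,10,1.02,1.02
diet_to_psych,white_bread,seen_psychiatrist,0.15,60,40,-0.83,10,90,-0.98,0.98
diet_to_psych,white_bread,sleeplessness_insomnia,-1.28,0,100,0.23,64,36,1.51,1.51
diet_to_psych,white_bread,tense_highly_strung,0.08,58,42,-0.51,28,72,-0.59,0.59
diet_to_psych,beef_intake,seen_psychiatrist,1.43,96,4,-0.94,8,92,-2.37,2.37
diet_to_psych,biscuit_cereal,fed_up_feelings,-0.41,26,74,0.29,76,24,0.71,0.71
diet_to_psych,biscuit_cereal,seen_psychiatrist,0.17,56,44,-0.01,50,50,-0.19,0.19
diet_to_psych,biscuit_cereal,sleeplessness_insomnia,0.50,74,26,-0.34,32,68,-0.85,0.85
diet_to_psych,biscuit_cereal,tense_highly_strung,0.25,62,38,-0.15,38,62,-0.41,0.41
diet_to_psych,brown_bread,loneliness_isolation,-0.35,20,80,0.34,66,34,0.69,0.69
diet_to_psych,brown_bread,sleeplessness_insomnia,0.52,70,30,-0.43,20,80,-0.96,0.96
diet_to_psych,brown_bread,tense_highly_strung,-0.97,32,68,0.71,82,18,1.68,1.68
diet_to_psych,cheese_intake,fed_up_feelings,-0.60,28,72,0.15,54,46,0.76,0.76
diet_to_psych,cheese_intake,loneliness_isolation,0.15,64,36,-0.40,22,78,-0.55,0.55
diet_to_psych,cheese_intake,tense_highly_strung,0.35,76,24,-0.25,28,72,-0.60,0.60
diet_to_psych,cooked_vegetable_intake,loneliness_isolation,0.09,56,44,1.63,98,2,1.54,1.54
diet_to_psych,cooked_vegetable_intake,sleeplessness_insomnia,-0.21,40,60,0.26,64,36,0.48,0.48
diet_to_psych,muesli,loneliness_isolation,-0.44,26,74,0.11,58,42,0.55,0.55
diet_to_psych,muesli,seen_psychiatrist,0.46,78,22,-0.30,42,58,-0.76,0.76
diet_to_psych,oat_cereal,loneliness_isolation,-0.29,28,72,0.46,84,16,0.75,0.75
diet_to_psych,other_bread,fed_up_feelings,-0.47,34,66,0.08,52,48,0.55,0.55
diet_to_psych,other_bread,loneliness_isolation,-0.26,34,66,0.62,82,18,0.89,0.89
diet_to_psych,other_bread,sleeplessness_insomnia,-1.72,0,100,0.38,70,30,2.10,2.10
diet_to_psych,processed_meat,sleeplessness_insomnia,-0.67,8,92,0.70,84,16,1.37,1.37
diet_to_psych,processed_meat,tense_highly_strung,-0.40,26,74,0.49,82,18,0.90,0.90
diet_to_psych,salt_added_to_food,loneliness_isolation,-0.19,40,60,0.26,68,32,0.46,0.46
diet_to_psych,sugary_cereal,loneliness_isolation,-1.36,0,100,0.59,94,6,1.95,1.95
diet_to_psych,sugary_cereal,seen_psychiatrist,-0.89,16,84,0.18,60,40,1.07,1.07
demo_to_diet,age,beef_intake,0.07,96,4,0.01,90,10,-0.0629,0.0629
demo_to_diet,age,biscuit_cereal,0.34,36,64,-0.43,56,44,-0.7703,0.7703
demo_to_diet,age,brown_bread,-0.40,10,90,-0.54,24,76,-0.1492,0.1492
demo_to_diet,age,cheese_intake,-0.06,12,88,0.05,94,6,0.1095,0.1095
demo_to_diet,age,cooked_vegetable_intake,0.02,96,4,0.11,100,0,0.0904,0.0904
demo_to_diet,age,muesli,0.40,76,24,-0.18,14,86,-0.5760,0.5760
demo_to_diet,age,oat_cereal,0.50,52,48,-0.86,6,94,-1.3583,1.3583
demo_to_diet,age,other_bread,-0.62,2,98,-0.02,22,78,0.6019,0.6019
demo_to_diet,age,processed_meat,0.03,88,12,-0.08,46,54,-0.1082,0.1082
demo_to_diet,age,salt_added_to_food,-0.19,6,94,0.07,40,60,0.2521,0.2521
demo_to_diet,age,sugary_cereal,-0.82,34,66,-0.80,16,84,0.0215,0.0215
demo_to_diet,age,white_bread,-1.50,12,88,-0.47,30,70,1.0318,1.0318
demo_to_diet,bmi,beef_intake,0.26,100,0,0.09,96,4,-0.17,0.17
demo_to_diet,bmi,biscuit_cereal,-1.05,14,86,-2.39,0,100,-1.34,1.34
demo_to_diet,bmi,brown_bread,1.98,100,0,-0.81,8,92,-2.79,2.79
demo_to_diet,bmi,cheese_intake,-0.48,0,100,-0.10,2,98,0.38,0.38
demo_to_diet,bmi,cooked_vegetable_intake,0.13,100,0,0.03,84,16,-0.10,0.10
demo_to_diet,bmi,muesli,-3.29,0,100,-3.07,0,100,0.22,0.22
demo_to_diet,bmi,oat_cereal,-0.92,12,88,-2.77,0,100,-1.85,1.85
demo_to_diet,bmi,other_bread,-0.46,28,72,-0.69,12,88,-0.23,0.23
demo_to_diet,bmi,processed_meat,0.53,100,0,0.04,70,30,-0.50,0.50
demo_to_diet,bmi,salt_added_to_food,0.27,98,2,0.19,96,4,-0.08,0.08
demo_to_diet,bmi,sugary_cereal,-1.03,8,92,-1.67,0,100,-0.64,0.64
demo_to_diet,bmi,white_bread,5.17,100,0,1.55,100,0,-3.62,3.62
psych_to_diet,fed_up_feelings,beef_intake,0.02,72,28,0.00,46,54,-0.02,0.02
psych_to_diet,fed_up_feelings,biscuit_cereal,-0.14,42,58,0.37,72,28,0.52,0.52
psych_to_diet,fed_up_feelings,cheese_intake,-0.05,26,74,0.05,74,26,0.10,0.10
psych_to_diet,loneliness_isolation,beef_intake,0.07,78,22,-0.07,12,88,-0.14,0.14
psych_to_diet,loneliness_isolation,biscuit_cereal,-0.33,24,76,0.38,84,16,0.72,0.72
psych_to_diet,loneliness_isolation,brown_bread,-0.19,32,68,0.19,68,32,0.38,0.38
psych_to_diet,loneliness_isolation,cooked_vegetable_intake,0.02,68,32,-0.04,18,82,-0.06,0.06
psych_to_diet,loneliness_isolation,muesli,-0.13,40,60,0.93,98,2,1.06,1.06
psych_to_diet,loneliness_isolation,oat_cereal,-0.76,10,90,1.00,92,8,1.77,1.77
psych_to_diet,loneliness_isolation,other_bread,-0.20,38,62,0.41,86,14,0.62,0.62
psych_to_diet,loneliness_isolation,sugary_cereal,-1.07,2,98,0.93,100,0,2.00,2.00
psych_to_diet,loneliness_isolation,white_bread,-0.81,10,90,0.08,54,46,0.90,0.90
psych_to_diet,seen_psychiatrist,beef_intake,0.08,86,14,0.00,48,52,-0.08,0.08
psych_to_diet,seen_psychiatrist,cheese_intake,-0.10,10,90,0.00,54,46,0.10,0.10
psych_to_diet,seen_psychiatrist,cooked_vegetable_intake,-0.03,20,80,0.01,62,38,0.05,0.05
psych_to_diet,seen_psychiatrist,white_bread,0.49,74,26,-0.72,16,84,-1.21,1.21
psych_to_diet,sleeplessness_insomnia,brown_bread,0.22,70,30,-0.47,14,86,-0.69,0.69
psych_to_diet,sleeplessness_insomnia,other_bread,-0.68,16,84,0.42,88,12,1.11,1.11
psych_to_diet,sleeplessness_insomnia,white_bread,-0.81,24,76,0.15,64,36,0.96,0.96
psych_to_diet,tense_highly_strung,brown_bread,-0.44,24,76,0.41,76,24,0.85,0.85
psych_to_diet,tense_highly_strung,cheese_intake,0.01,60,40,0.00,44,56,-0.02,0.02
psych_to_diet,tense_highly_strung,other_bread,-0.61,26,74,0.05,56,44,0.66,0.66
psych_to_diet,tense_highly_strung,processed_meat,-0.08,20,80,0.02,62,38,0.11,0.11
psych_to_diet,tense_highly_strung,white_bread,0.38,70,30,-0.35,28,72,-0.73,0.73
demo_to_psych,age,fed_up_feelings,-1.02,6,94,-1.75,0,100,-0.73,0.73
demo_to_psych,age,loneliness_isolation,-1.79,0,100,-0.65,8,92,1.14,1.14
demo_to_psych,age,seen_psychiatrist,0.21,76,24,-0.30,20,80,-0.51,0.51
demo_to_psych,age,sleeplessness_insomnia,1.88,100,0,0.82,88,12,-1.05,1.05
demo_to_psych,age,tense_highly_strung,-0.59,24,76,-0.08,48,52,0.51,0.51
demo_to_psych,bmi,fed_up_feelings,3.14,100,0,2.20,100,0,-0.94,0.94
demo_to_psych,bmi,loneliness_isolation,0.43,68,32,1.55,100,0,1.11,1.11
demo_to_psych,bmi,seen_psychiatrist,-0.22,44,56,0.03,54,46,0.26,0.26
demo_to_psych,bmi,sleeplessness_insomnia,2.08,100,0,2.44,100,0,0.36,0.36
demo_to_psych,bmi,tense_highly_strung,-3.51,0,100,-2.36,0,100,1.14,1.14
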