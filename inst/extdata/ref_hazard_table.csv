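name,beta,hr,hr_pct,p,ci_low,ci_high
loneliness_isolation,0.13,1.14,14.00,0.001,1.07,1.21
seen_psychiatrist,0.16,1.18,18.00,0.001,1.09,1.27
sleeplessness_insomnia,0.06,1.06,6.00,0.02,1.00,1.12
fed_up_feelings,0.08,1.08,8.00,0.001,1.02,1.14
tense_highly_strung,0.15,1.17,17.00,0.001,1.10,1.25
sleep_duration_7_8h,-0.13,0.87,-13.00,0.001,0.82,0.93
nap_during_day,0.09,1.10,10.00,0.001,1.01,1.20
difficulty_getting_up,0.04,1.04,4.00,0.001,1.01,1.08
plays_computer_games,0.04,1.04,4.00,0.01,1.01,1.07
smoking_status.previous,0.12,1.13,13.00,0.001,1.07,1.19
smoking_status.current,0.17,1.19,19.00,0.01,1.02,1.38
current_tobacco_smoking,0.29,1.34,34.00,0.001,1.14,1.58
salt_added_to_food,0.04,1.05,5.00,0.001,1.02,1.08
cheese_intake,-0.05,0.94,-6.00,0.001,0.92,0.96
bread_type.brown,0.16,1.18,18.00,0.001,1.09,1.27
bread_type.white,0.26,1.30,30.00,0.001,1.18,1.43
bread_type.other,0.11,1.11,11.00,0.07,0.98,1.26
processed_meat.lt_once_week,0.07,1.07,7.00,0.15,0.97,1.19
processed_meat.once_week,0.05,1.05,5.00,0.29,0.95,1.17
processed_meat.two_to_four_week,0.06,1.06,6.00,0.21,0.96,1.18
processed_meat.five_to_six_week,0.17,1.18,18.00,0.03,1.01,1.38
beef_intake.five_to_six_week,0.16,1.18,18.00,0.001,1.08,1.29
cereal_type.biscuit,0.10,1.11,11.00,0.01,1.02,1.21
cereal_type.oat,-0.23,0.79,-21.00,0.001,0.73,0.85
cereal_type.muesli,-0.55,0.57,-43.00,0.001,0.52,0.63
cereal_type.sugary,0.10,1.11,11.00,0.01,1.02,1.21
age.50_59,-0.06,0.93,-7.00,0.50,0.75,1.14
age.60_70,0.42,1.52,52.00,0.001,1.24,1.87
bmi.25_29.9,-0.71,0.49,-51.00,0.001,0.39,0.60
bmi.30_34.9,0.08,1.08,8.00,0.40,0.88,1.33
bmi.35_39.9,0.43,1.54,54.00,0.001,1.26,1.89
bmi.40_50,0.58,1.79,79.00,0.001,1.45,2.20
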