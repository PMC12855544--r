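variable,in_degree_healthy,in_degree_t2dm,in_degree_delta,out_degree_healthy,out_degree_t2dm,out_degree_delta,eigenvector_healthy,eigenvector_t2dm,eigenvector_delta
age,0.52,0.36,-0.16,0.48,0.40,-0.08,0.24,0.10,-0.14
beef_intake,0.64,0.64,0.00,0.72,0.72,0.00,0.21,0.12,-0.09
bmi,0.56,0.56,0.00,0.44,0.56,0.12,0.47,0.18,-0.29
brown_bread,0.40,0.32,-0.08,0.36,0.44,0.08,0.03,0.04,0.01
biscuit_cereal,0.44,0.48,0.04,0.52,0.64,0.12,0.09,0.02,-0.07
muesli,0.48,0.20,-0.28,0.60,0.36,-0.24,0.07,0.01,-0.07
oat_cereal,0.40,0.28,-0.12,0.56,0.48,-0.08,0.08,0.05,-0.03
sugary_cereal,0.32,0.36,0.04,0.52,0.56,0.04,0.05,0.05,0.00
cheese_intake,0.64,0.64,0.00,0.32,0.48,0.16,0.12,0.03,-0.09
cooked_vegetable_intake,0.40,0.60,0.20,0.36,0.40,0.04,0.11,0.08,-0.03
current_tobacco_smoking,0.44,0.72,0.28,0.28,0.52,0.24,0.43,0.87,0.44
fed_up_feelings,0.64,0.56,-0.08,0.44,0.60,0.16,0.31,0.15,-0.16
difficulty_getting_up,0.48,0.56,0.08,0.60,0.52,-0.08,0.05,0.03,-0.03
loneliness_isolation,0.40,0.60,0.20,0.36,0.48,0.12,0.25,0.14,-0.11
long_standing_illness,0.56,0.60,0.04,0.56,0.60,0.04,0.14,0.10,-0.04
nap_during_day,0.52,0.52,0.00,0.52,0.48,-0.04,0.16,0.05,-0.11
other_bread,0.40,0.56,0.16,0.40,0.52,0.12,0.11,0.08,-0.03
processed_meat,0.52,0.80,0.28,0.56,0.68,0.12,0.14,0.18,0.03
salt_added_to_food,0.56,0.72,0.16,0.48,0.64,0.16,0.19,0.09,-0.11
seen_psychiatrist,0.56,0.60,0.04,0.60,0.52,-0.08,0.28,0.14,-0.14
sleep_duration_7_8h,0.52,0.32,-0.20,0.60,0.52,-0.08,0.05,0.00,-0.04
sleeplessness_insomnia,0.48,0.56,0.08,0.52,0.64,0.12,0.11,0.09,-0.02
smoking_status,0.64,0.72,0.08,0.76,0.84,0.08,0.12,0.15,0.03
tense_highly_strung,0.44,0.48,0.04,0.40,0.32,-0.08,0.22,0.12,-0.10
white_bread,0.52,0.56,0.04,0.56,0.60,0.04,0.10,0.05,-0.05
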