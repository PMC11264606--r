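# instrument=PROPr
# variant=synthetic tabulated curves
# util_best=0.954
# util_worst=-0.022
# weight.physical_function=0.626
# weight.pain_interference=0.616
# weight.depression=0.666
# weight.fatigue=0.639
# weight.social_roles=0.657
# weight.sleep_disturbance=0.630
# weight.cognitive_function=0.635
domain,score,disutility
physical_function,58.000,0.000000
physical_function,52.750,0.035897
physical_function,47.500,0.108819
physical_function,42.250,0.208185
physical_function,37.000,0.329877
physical_function,31.750,0.471420
physical_function,26.500,0.631100
physical_function,21.250,0.807631
physical_function,16.000,1.000000
pain_interference,38.000,0.000000
pain_interference,43.500,0.035897
pain_interference,49.000,0.108819
pain_interference,54.500,0.208185
pain_interference,60.000,0.329877
pain_interference,65.500,0.471420
pain_interference,71.000,0.631100
pain_interference,76.500,0.807631
pain_interference,82.000,1.000000
depression,38.000,0.000000
depression,43.500,0.035897
depression,49.000,0.108819
depression,54.500,0.208185
depression,60.000,0.329877
depression,65.500,0.471420
depression,71.000,0.631100
depression,76.500,0.807631
depression,82.000,1.000000
fatigue,38.000,0.000000
fatigue,43.500,0.035897
fatigue,49.000,0.108819
fatigue,54.500,0.208185
fatigue,60.000,0.329877
fatigue,65.500,0.471420
fatigue,71.000,0.631100
fatigue,76.500,0.807631
fatigue,82.000,1.000000
social_roles,64.000,0.000000
social_roles,58.750,0.035897
social_roles,53.500,0.108819
social_roles,48.250,0.208185
social_roles,43.000,0.329877
social_roles,37.750,0.471420
social_roles,32.500,0.631100
social_roles,27.250,0.807631
social_roles,22.000,1.000000
sleep_disturbance,38.000,0.000000
sleep_disturbance,43.500,0.035897
sleep_disturbance,49.000,0.108819
sleep_disturbance,54.500,0.208185
sleep_disturbance,60.000,0.329877
sleep_disturbance,65.500,0.471420
sleep_disturbance,71.000,0.631100
sleep_disturbance,76.500,0.807631
sleep_disturbance,82.000,1.000000
cognitive_function,60.000,0.000000
cognitive_function,54.750,0.035897
cognitive_function,49.500,0.108819
cognitive_function,44.250,0.208185
cognitive_function,39.000,0.329877
cognitive_function,33.750,0.471420
cognitive_function,28.500,0.631100
cognitive_function,23.250,0.807631
cognitive_function,18.000,1.000000
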