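# source=U.S. general-population baseline survey (n=4098)
# propr_intercept=0.692
# eq5d_intercept=0.974
# propr_r_squared=0.41
# eq5d_r_squared=0.39
condition,prevalence,propr_beta,propr_zero_order,eq5d_beta,eq5d_zero_order
hypertension,0.38,-0.009,-0.16,-0.024,-0.20
high_cholesterol,0.38,0.015,-0.11,0.001,-0.13
heart_disease,0.06,-0.001,-0.07,-0.004,-0.09
angina,0.02,-0.022,-0.09,-0.025,-0.10
heart_attack,0.03,-0.001,-0.06,-0.001,-0.07
stroke,0.03,-0.030,-0.08,-0.058,-0.11
asthma,0.13,-0.013,-0.14,-0.009,-0.13
cancer,0.10,0.020,-0.03,0.009,-0.05
diabetes,0.13,-0.057,-0.16,-0.032,-0.17
copd,0.05,-0.044,-0.15,-0.069,-0.19
arthritis,0.30,-0.031,-0.26,-0.046,-0.32
anxiety,0.20,-0.055,-0.35,-0.041,-0.34
depression,0.20,-0.112,-0.46,-0.078,-0.38
allergies,0.45,0.012,-0.15,0.015,-0.14
back_pain,0.38,-0.069,-0.37,-0.052,-0.38
sciatica,0.17,-0.057,-0.31,-0.077,-0.36
neck_pain,0.20,-0.029,-0.29,-0.025,-0.30
trouble_seeing,0.15,-0.061,-0.29,-0.047,-0.27
dermatitis,0.10,-0.044,-0.16,-0.030,-0.16
stomach_trouble,0.15,-0.039,-0.29,-0.039,-0.29
trouble_hearing,0.15,-0.014,-0.15,-0.009,-0.16
trouble_sleeping,0.15,-0.152,-0.46,-0.065,-0.36
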