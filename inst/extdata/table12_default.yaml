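seed: 7
n_neg: 33
n_pos: 69
age:
  mean_neg: 66.9
  sd_neg: 8.6
  mean_pos: 73.0
  sd_pos: 6.1
education:
  mean_neg: 10.4
  sd_neg: 3.1
  mean_pos: 9.4
  sd_pos: 4.2
mmse:
  mean_neg: 24.2
  sd_neg: 4.16
  mean_pos: 22.4
  sd_pos: 4.21
male_prob:
  neg: 0.3636364
  pos: 0.5507246
apoe_e4_prob:
  neg: 0.1818182
  pos: 0.4927536
mci_prob:
  neg: 0.36
  pos: 0.5074627
missing_diagnosis_rate: 0.0980392
csf_ratio:
  mean_neg: 0.09
  sd_neg: 0.01
  mean_pos: 0.05
  sd_pos: 0.01
  cutoff: 0.069
  max_attempts: 10000
biomarkers:
- name: csf_ab42
  mean_neg: 966.09
  sd_neg: 410.34
  mean_pos: 555.58
  sd_pos: 220.33
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
- name: csf_ttau
  mean_neg: 335.48
  sd_neg: 139.22
  mean_pos: 643.63
  sd_pos: 294.15
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
- name: csf_ptau181
  mean_neg: 39.26
  sd_neg: 16.14
  mean_pos: 113.6
  sd_pos: 62.01
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
- name: plasma_ab42
  mean_neg: 30.91
  sd_neg: 7.51
  mean_pos: 21.41
  sd_pos: 9.56
  family: lognormal
  outlier_rate: 0.05
  outlier_scale: 3.0
- name: plasma_ab40
  mean_neg: 347.99
  sd_neg: 83.24
  mean_pos: 301.99
  sd_pos: 127.55
  family: lognormal
  outlier_rate: 0.05
  outlier_scale: 3.0
- name: plasma_ptau181
  mean_neg: 1.68
  sd_neg: 0.64
  mean_pos: 3.28
  sd_pos: 1.77
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
- name: plasma_ptau217
  mean_neg: 0.18
  sd_neg: 0.11
  mean_pos: 0.83
  sd_pos: 0.56
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
- name: plasma_nfl
  mean_neg: 47.73
  sd_neg: 34.24
  mean_pos: 34.78
  sd_pos: 28.84
  family: lognormal
  outlier_rate: 0.0
  outlier_scale: 1.0
correlation:
  within: 0.7
  across: 0.3
mmse_model: ~
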