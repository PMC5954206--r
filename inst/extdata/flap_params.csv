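label,c10_pa,k1_pa,k2,alpha_deg,kappa,thickness_mm
mid_flap_1,92963,230290,13.9,87.1,0.33,0.58
mid_flap_2,73144,235075,7.86,68.7,0.3,0.59
mid_flap_3,64042,212120,4.99,23.5,0.32,0.54
mid_flap_4,52072,125430,5.87,53.9,0.26,0.70
mid_flap_5,45588,149880,1.42,55.6,0.21,0.47
distal_flap_1,103140,61969,4.1,62.4,0.1,0.4
distal_flap_2,171740,661830,8.05,86.5,0.3,0.34
distal_flap_3,78686,239090,3.18,89.9,0.3,0.43
distal_flap_4,63554,77013,4.76,83.4,0.11,0.29
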