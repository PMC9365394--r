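spindle,pole_distance_um,interkin_mean_um,interkin_sd_um,interkin_n,n_mts,n_kinetochores,n_kmts,n_nonkmts,n_kfibers,kmt_length_um,kmt_length_sd_um,nonkmt_length_um,kmts_per_kinetochore,kmts_per_kinetochore_sd,kmt_minus_dist_um,pct_kmts_pole_assoc,pct_nonkmts_pole_assoc,kmt_density_per_um2,kmt_spacing_nm,global_tortuosity,pct_curved_kmts,kfiber_area_um2,pct_kmts_in_fiber
1,7.16,1.08,0.20,43,4884,92,797,4087,92,3.59,1.57,2.13,8.04,1.86,1.72,61.2,44.3,122,67,1.11,39.8,0.08,64
2,10.39,1.24,0.21,50,8047,110,1102,6945,110,3.82,1.97,1.95,9.75,2.18,2.87,31.5,28.6,99,78,1.07,28.4,0.09,70
3,9.48,1.03,0.27,40,5904,90,680,5224,90,4.27,1.93,2.07,7.49,1.91,2.12,54.2,41.9,117,76,1.13,47.1,0.12,59
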