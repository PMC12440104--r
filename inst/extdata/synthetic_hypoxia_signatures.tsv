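signature	gene
hypoxia_buffa_syn	HYPX_A_1
hypoxia_buffa_syn	HYPX_A_2
hypoxia_buffa_syn	HYPX_A_3
hypoxia_buffa_syn	HYPX_A_4
hypoxia_buffa_syn	HYPX_A_5
hypoxia_buffa_syn	HYPX_A_6
hypoxia_buffa_syn	HYPX_A_7
hypoxia_buffa_syn	HYPX_A_8
hypoxia_buffa_syn	HYPX_A_9
hypoxia_buffa_syn	HYPX_A_10
hypoxia_buffa_syn	HYPX_A_11
hypoxia_buffa_syn	HYPX_A_12
hypoxia_buffa_syn	HYPX_A_13
hypoxia_buffa_syn	HYPX_A_14
hypoxia_buffa_syn	HYPX_A_15
hypoxia_winter_syn	HYPX_B_1
hypoxia_winter_syn	HYPX_B_2
hypoxia_winter_syn	HYPX_B_3
hypoxia_winter_syn	HYPX_B_4
hypoxia_winter_syn	HYPX_B_5
hypoxia_winter_syn	HYPX_B_6
hypoxia_winter_syn	HYPX_B_7
hypoxia_winter_syn	HYPX_B_8
hypoxia_winter_syn	HYPX_B_9
hypoxia_winter_syn	HYPX_B_10
hypoxia_winter_syn	HYPX_B_11
hypoxia_winter_syn	HYPX_B_12
hypoxia_winter_syn	HYPX_B_13
hypoxia_winter_syn	HYPX_B_14
hypoxia_winter_syn	HYPX_B_15
hypoxia_ragnum_syn	HYPX_C_1
hypoxia_ragnum_syn	HYPX_C_2
hypoxia_ragnum_syn	HYPX_C_3
hypoxia_ragnum_syn	HYPX_C_4
hypoxia_ragnum_syn	HYPX_C_5
hypoxia_ragnum_syn	HYPX_C_6
hypoxia_ragnum_syn	HYPX_C_7
hypoxia_ragnum_syn	HYPX_C_8
hypoxia_ragnum_syn	HYPX_C_9
hypoxia_ragnum_syn	HYPX_C_10
hypoxia_ragnum_syn	HYPX_C_11
hypoxia_ragnum_syn	HYPX_C_12
hypoxia_ragnum_syn	HYPX_C_13
hypoxia_ragnum_syn	HYPX_C_14
hypoxia_ragnum_syn	HYPX_C_15
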