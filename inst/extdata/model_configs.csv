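model,data_fusion,joint_structure,shared_fixed,indep_fixed,spatial_spde,shared_st,species_st,svc
M1,0,0,0,0,0,0,0,0
M2,0,0,1,0,1,0,0,0
M3,0,0,1,0,0,1,0,0
M4,0,1,1,0,0,1,0,0
M5,0,1,1,0,0,1,0,0
M6,0,1,1,0,0,0,1,0
M7,0,1,1,0,0,1,0,1
M8,0,1,1,0,0,0,1,1
M9,1,1,1,0,0,1,0,0
M10,1,1,1,0,0,0,1,0
M11,1,1,0,1,0,1,0,0
M12,1,1,0,1,0,0,1,0
M13,1,1,1,0,0,1,1,0
M14,1,1,0,1,0,1,1,0
M15,1,1,1,0,0,1,0,1
M16,1,1,1,0,0,0,1,1
M17,1,1,0,1,0,1,0,1
M18,1,1,0,1,0,0,1,1
M19,1,1,1,0,0,1,1,1
M20,1,1,0,1,0,1,1,1
M21,0,1,1,0,0,1,1,0
M22,0,1,0,1,0,1,1,0
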