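supertarget,protein,n_pose_with_affinity,n_pose_structure_only,n_pose_excluded,n_affinity_stage1,n_affinity_stage2,n_disclosed
L1000,chymase,17,0,0,17,17,3
L2000,cathepsin_g,0,2,0,0,0,0
L3000,autotaxin,93,96,0,123,93,15
L4000,mpro,0,25,5,0,0,0
L5000,wdr55,0,1,0,0,0,0
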