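name	lobe	hemisphere
Precentral_L	frontal	L
Precentral_R	frontal	R
Frontal_Sup_L	frontal	L
Frontal_Sup_R	frontal	R
Frontal_Sup_Orb_L	frontal	L
Frontal_Sup_Orb_R	frontal	R
Frontal_Mid_L	frontal	L
Frontal_Mid_R	frontal	R
Frontal_Mid_Orb_L	frontal	L
Frontal_Mid_Orb_R	frontal	R
Frontal_Inf_Oper_L	frontal	L
Frontal_Inf_Oper_R	frontal	R
Frontal_Inf_Tri_L	frontal	L
Frontal_Inf_Tri_R	frontal	R
Frontal_Inf_Orb_L	frontal	L
Frontal_Inf_Orb_R	frontal	R
Rolandic_Oper_L	frontal	L
Rolandic_Oper_R	frontal	R
Supp_Motor_Area_L	frontal	L
Supp_Motor_Area_R	frontal	R
Olfactory_L	frontal	L
Olfactory_R	frontal	R
Frontal_Sup_Medial_L	frontal	L
Frontal_Sup_Medial_R	frontal	R
Frontal_Med_Orb_L	frontal	L
Frontal_Med_Orb_R	frontal	R
Rectus_L	frontal	L
Rectus_R	frontal	R
Paracentral_Lobule_L	frontal	L
Paracentral_Lobule_R	frontal	R
Insula_L	limbic	L
Insula_R	limbic	R
Cingulate_Ant_L	limbic	L
Cingulate_Ant_R	limbic	R
Cingulate_Mid_L	limbic	L
Cingulate_Mid_R	limbic	R
Cingulate_Post_L	limbic	L
Cingulate_Post_R	limbic	R
Hippocampus_L	limbic	L
Hippocampus_R	limbic	R
ParaHippocampal_L	limbic	L
ParaHippocampal_R	limbic	R
Amygdala_L	limbic	L
Amygdala_R	limbic	R
Caudate_L	limbic	L
Caudate_R	limbic	R
Putamen_L	limbic	L
Putamen_R	limbic	R
Pallidum_L	limbic	L
Pallidum_R	limbic	R
Thalamus_L	limbic	L
Thalamus_R	limbic	R
Postcentral_L	parietal	L
Postcentral_R	parietal	R
Parietal_Sup_L	parietal	L
Parietal_Sup_R	parietal	R
Parietal_Inf_L	parietal	L
Parietal_Inf_R	parietal	R
SupraMarginal_L	parietal	L
SupraMarginal_R	parietal	R
Angular_L	parietal	L
Angular_R	parietal	R
Precuneus_L	parietal	L
Precuneus_R	parietal	R
Heschl_L	temporal	L
Heschl_R	temporal	R
Temporal_Sup_L	temporal	L
Temporal_Sup_R	temporal	R
Temporal_Pole_Sup_L	temporal	L
Temporal_Pole_Sup_R	temporal	R
Temporal_Mid_L	temporal	L
Temporal_Mid_R	temporal	R
Temporal_Pole_Mid_L	temporal	L
Temporal_Pole_Mid_R	temporal	R
Temporal_Inf_L	temporal	L
Temporal_Inf_R	temporal	R
Calcarine_L	occipital	L
Calcarine_R	occipital	R
Cuneus_L	occipital	L
Cuneus_R	occipital	R
Lingual_L	occipital	L
Lingual_R	occipital	R
Occipital_Sup_L	occipital	L
Occipital_Sup_R	occipital	R
Occipital_Mid_L	occipital	L
Occipital_Mid_R	occipital	R
Occipital_Inf_L	occipital	L
Occipital_Inf_R	occipital	R
Fusiform_L	occipital	L
Fusiform_R	occipital	R
Cerebellum_Crus1_L	cerebellum	L
Cerebellum_Crus1_R	cerebellum	R
Cerebellum_Crus2_L	cerebellum	L
Cerebellum_Crus2_R	cerebellum	R
Cerebellum_3_L	cerebellum	L
Cerebellum_3_R	cerebellum	R
Cerebellum_4_5_L	cerebellum	L
Cerebellum_4_5_R	cerebellum	R
Cerebellum_6_L	cerebellum	L
Cerebellum_6_R	cerebellum	R
Cerebellum_7b_L	cerebellum	L
Cerebellum_7b_R	cerebellum	R
Cerebellum_8_L	cerebellum	L
Cerebellum_8_R	cerebellum	R
Cerebellum_9_L	cerebellum	L
Cerebellum_9_R	cerebellum	R
Cerebellum_10_L	cerebellum	L
Cerebellum_10_R	cerebellum	R
Vermis_4_5	cerebellum	M
Vermis_6	cerebellum	M
Vermis_8	cerebellum	M
Vermis_9	cerebellum	M
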