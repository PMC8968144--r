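parcel,legend,group,hemisphere
lh_G_and_S_frontomargin,G&S frontomargin L,Fro-L,L
lh_G_and_S_paracentral,G&S paracentral L,Fro-L,L
lh_G_and_S_subcentral,G&S subcentral L,Fro-L,L
lh_G_and_S_transv_frontopol,G&S transv frontopol L,Fro-L,L
lh_G_front_inf-Opercular,G front inf Opercular L,Fro-L,L
lh_G_front_inf-Orbital,G front inf Orbital L,Fro-L,L
lh_G_front_inf-Triangul,G front inf Triangul L,Fro-L,L
lh_G_front_middle,G front middle L,Fro-L,L
lh_G_front_sup,G front sup L,Fro-L,L
lh_G_orbital,G orbital L,Fro-L,L
lh_G_precentral,G precentral L,Fro-L,L
lh_G_rectus,G rectus L,Fro-L,L
lh_S_central,S central L,Fro-L,L
lh_S_front_inf,S front inf L,Fro-L,L
lh_S_front_middle,S front middle L,Fro-L,L
lh_S_front_sup,S front sup L,Fro-L,L
lh_S_orbital_lateral,S orbital lateral L,Fro-L,L
lh_S_orbital_med-olfact,S orbital med olfact L,Fro-L,L
lh_S_orbital-H_Shaped,S orbital H Shaped L,Fro-L,L
lh_S_precentral-inf-part,S precentral inf part L,Fro-L,L
lh_S_precentral-sup-part,S precentral sup part L,Fro-L,L
lh_G_Ins_lg_and_S_cent_ins,G Ins lg&S cent ins L,Ins-L,L
lh_G_insular_short,G insular short L,Ins-L,L
lh_S_circular_insula_ant,S circular insula ant L,Ins-L,L
lh_S_circular_insula_inf,S circular insula inf L,Ins-L,L
lh_S_circular_insula_sup,S circular insula sup L,Ins-L,L
lh_G_and_S_cingul-Ant,G&S cingul Ant L,Lim-L,L
lh_G_and_S_cingul-Mid-Ant,G&S cingul Mid Ant L,Lim-L,L
lh_G_and_S_cingul-Mid-Post,G&S cingul Mid Post L,Lim-L,L
lh_G_cingul-Post-dorsal,G cingul Post dorsal L,Lim-L,L
lh_G_cingul-Post-ventral,G cingul Post ventral L,Lim-L,L
lh_G_subcallosal,G subcallosal L,Lim-L,L
lh_Medial_wall,Medial wall L,Lim-L,L
lh_S_cingul-Marginalis,S cingul Marginalis L,Lim-L,L
lh_S_pericallosal,S pericallosal L,Lim-L,L
lh_S_suborbital,S suborbital L,Lim-L,L
lh_G_oc-temp_lat-fusifor,G oc temp lat fusifor L,Tem-L,L
lh_G_oc-temp_med-Lingual,G oc temp med Lingual L,Tem-L,L
lh_G_oc-temp_med-Parahip,G oc temp med Parahip L,Tem-L,L
lh_G_temp_sup-G_T_transv,G temp sup G T transv L,Tem-L,L
lh_G_temp_sup-Lateral,G temp sup Lateral L,Tem-L,L
lh_G_temp_sup-Plan_polar,G temp sup Plan polar L,Tem-L,L
lh_G_temp_sup-Plan_tempo,G temp sup Plan tempo L,Tem-L,L
lh_G_temporal_inf,G temporal inf L,Tem-L,L
lh_G_temporal_middle,G temporal middle L,Tem-L,L
lh_Lat_Fis-ant-Horizont,Lat Fis ant Horizont L,Tem-L,L
lh_Lat_Fis-ant-Vertical,Lat Fis ant Vertical L,Tem-L,L
lh_Lat_Fis-post,Lat Fis post L,Tem-L,L
lh_Pole_temporal,Pole temporal L,Tem-L,L
lh_S_collat_transv_ant,S collat transv ant L,Tem-L,L
lh_S_oc-temp_lat,S oc temp lat L,Tem-L,L
lh_S_oc-temp_med_and_Lingual,S oc temp med&Lingual L,Tem-L,L
lh_S_temporal_inf,S temporal inf L,Tem-L,L
lh_S_temporal_sup,S temporal sup L,Tem-L,L
lh_S_temporal_transverse,S temporal transverse L,Tem-L,L
lh_G_pariet_inf-Angular,G pariet inf Angular L,Par-L,L
lh_G_pariet_inf-Supramar,G pariet inf Supramar L,Par-L,L
lh_G_parietal_sup,G parietal sup L,Par-L,L
lh_G_postcentral,G postcentral L,Par-L,L
lh_G_precuneus,G precuneus L,Par-L,L
lh_S_interm_prim-Jensen,S interm prim Jensen L,Par-L,L
lh_S_intrapariet_and_P_trans,S intrapariet&P trans L,Par-L,L
lh_S_parieto_occipital,S parieto occipital L,Par-L,L
lh_S_postcentral,S postcentral L,Par-L,L
lh_S_subparietal,S subparietal L,Par-L,L
lh_G_and_S_occipital_inf,G&S occipital inf L,Occ-L,L
lh_G_cuneus,G cuneus L,Occ-L,L
lh_G_occipital_middle,G occipital middle L,Occ-L,L
lh_G_occipital_sup,G occipital sup L,Occ-L,L
lh_Pole_occipital,Pole occipital L,Occ-L,L
lh_S_calcarine,S calcarine L,Occ-L,L
lh_S_collat_transv_post,S collat transv post L,Occ-L,L
lh_S_oc_middle_and_Lunatus,S oc middle&Lunatus L,Occ-L,L
lh_S_oc_sup_and_transversal,S oc sup&transversal L,Occ-L,L
lh_S_occipital_ant,S occipital ant L,Occ-L,L
Left-Thalamus,Thalamus L,Sbc-L,L
Left-Caudate,Caudate L,Sbc-L,L
Left-Putamen,Putamen L,Sbc-L,L
Left-Pallidum,Pallidum L,Sbc-L,L
Left-Accumbens,Accumbens L,Sbc-L,L
Left-Amygdala,Amygdala L,Sbc-L,L
Left-Hippocampus,Hippocampus L,Sbc-L,L
Brain-Stem,Brainstem,Bst,M
Right-Hippocampus,Hippocampus R,Sbc-R,R
Right-Amygdala,Amygdala R,Sbc-R,R
Right-Accumbens,Accumbens R,Sbc-R,R
Right-Pallidum,Pallidum R,Sbc-R,R
Right-Putamen,Putamen R,Sbc-R,R
Right-Caudate,Caudate R,Sbc-R,R
Right-Thalamus,Thalamus R,Sbc-R,R
rh_G_and_S_occipital_inf,G&S occipital inf R,Occ-R,R
rh_G_cuneus,G cuneus R,Occ-R,R
rh_G_occipital_middle,G occipital middle R,Occ-R,R
rh_G_occipital_sup,G occipital sup R,Occ-R,R
rh_Pole_occipital,Pole occipital R,Occ-R,R
rh_S_calcarine,S calcarine R,Occ-R,R
rh_S_collat_transv_post,S collat transv post R,Occ-R,R
rh_S_oc_middle_and_Lunatus,S oc middle&Lunatus R,Occ-R,R
rh_S_oc_sup_and_transversal,S oc sup&transversal R,Occ-R,R
rh_S_occipital_ant,S occipital ant R,Occ-R,R
rh_G_pariet_inf-Angular,G pariet inf Angular R,Par-R,R
rh_G_pariet_inf-Supramar,G pariet inf Supramar R,Par-R,R
rh_G_parietal_sup,G parietal sup R,Par-R,R
rh_G_postcentral,G postcentral R,Par-R,R
rh_G_precuneus,G precuneus R,Par-R,R
rh_S_interm_prim-Jensen,S interm prim Jensen R,Par-R,R
rh_S_intrapariet_and_P_trans,S intrapariet&P trans R,Par-R,R
rh_S_parieto_occipital,S parieto occipital R,Par-R,R
rh_S_postcentral,S postcentral R,Par-R,R
rh_S_subparietal,S subparietal R,Par-R,R
rh_G_oc-temp_lat-fusifor,G oc temp lat fusifor R,Tem-R,R
rh_G_oc-temp_med-Lingual,G oc temp med Lingual R,Tem-R,R
rh_G_oc-temp_med-Parahip,G oc temp med Parahip R,Tem-R,R
rh_G_temp_sup-G_T_transv,G temp sup G T transv R,Tem-R,R
rh_G_temp_sup-Lateral,G temp sup Lateral R,Tem-R,R
rh_G_temp_sup-Plan_polar,G temp sup Plan polar R,Tem-R,R
rh_G_temp_sup-Plan_tempo,G temp sup Plan tempo R,Tem-R,R
rh_G_temporal_inf,G temporal inf R,Tem-R,R
rh_G_temporal_middle,G temporal middle R,Tem-R,R
rh_Lat_Fis-ant-Horizont,Lat Fis ant Horizont R,Tem-R,R
rh_Lat_Fis-ant-Vertical,Lat Fis ant Vertical R,Tem-R,R
rh_Lat_Fis-post,Lat Fis post R,Tem-R,R
rh_Pole_temporal,Pole temporal R,Tem-R,R
rh_S_collat_transv_ant,S collat transv ant R,Tem-R,R
rh_S_oc-temp_lat,S oc temp lat R,Tem-R,R
rh_S_oc-temp_med_and_Lingual,S oc temp med&Lingual R,Tem-R,R
rh_S_temporal_inf,S temporal inf R,Tem-R,R
rh_S_temporal_sup,S temporal sup R,Tem-R,R
rh_S_temporal_transverse,S temporal transverse R,Tem-R,R
rh_G_and_S_cingul-Ant,G&S cingul Ant R,Lim-R,R
rh_G_and_S_cingul-Mid-Ant,G&S cingul Mid Ant R,Lim-R,R
rh_G_and_S_cingul-Mid-Post,G&S cingul Mid Post R,Lim-R,R
rh_G_cingul-Post-dorsal,G cingul Post dorsal R,Lim-R,R
rh_G_cingul-Post-ventral,G cingul Post ventral R,Lim-R,R
rh_G_subcallosal,G subcallosal R,Lim-R,R
rh_Medial_wall,Medial wall R,Lim-R,R
rh_S_cingul-Marginalis,S cingul Marginalis R,Lim-R,R
rh_S_pericallosal,S pericallosal R,Lim-R,R
rh_S_suborbital,S suborbital R,Lim-R,R
rh_G_Ins_lg_and_S_cent_ins,G Ins lg&S cent ins R,Ins-R,R
rh_G_insular_short,G insular short R,Ins-R,R
rh_S_circular_insula_ant,S circular insula ant R,Ins-R,R
rh_S_circular_insula_inf,S circular insula inf R,Ins-R,R
rh_S_circular_insula_sup,S circular insula sup R,Ins-R,R
rh_G_and_S_frontomargin,G&S frontomargin R,Fro-R,R
rh_G_and_S_paracentral,G&S paracentral R,Fro-R,R
rh_G_and_S_subcentral,G&S subcentral R,Fro-R,R
rh_G_and_S_transv_frontopol,G&S transv frontopol R,Fro-R,R
rh_G_front_inf-Opercular,G front inf Opercular R,Fro-R,R
rh_G_front_inf-Orbital,G front inf Orbital R,Fro-R,R
rh_G_front_inf-Triangul,G front inf Triangul R,Fro-R,R
rh_G_front_middle,G front middle R,Fro-R,R
rh_G_front_sup,G front sup R,Fro-R,R
rh_G_orbital,G orbital R,Fro-R,R
rh_G_precentral,G precentral R,Fro-R,R
rh_G_rectus,G rectus R,Fro-R,R
rh_S_central,S central R,Fro-R,R
rh_S_front_inf,S front inf R,Fro-R,R
rh_S_front_middle,S front middle R,Fro-R,R
rh_S_front_sup,S front sup R,Fro-R,R
rh_S_orbital_lateral,S orbital lateral R,Fro-R,R
rh_S_orbital_med-olfact,S orbital med olfact R,Fro-R,R
rh_S_orbital-H_Shaped,S orbital H Shaped R,Fro-R,R
rh_S_precentral-inf-part,S precentral inf part R,Fro-R,R
rh_S_precentral-sup-part,S precentral sup part R,Fro-R,R
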