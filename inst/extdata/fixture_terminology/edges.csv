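child_code,parent_code
grp_ili,resp_cond
grp_ecld,resp_cond
grp_lrti,resp_cond
grp_urti,resp_cond
grp_arinos,resp_cond
c_ili,grp_ili
c_ili_01,c_ili
c_ili_02,c_ili
c_ili_03,c_ili
c_ili_04,c_ili_01
c_ecld_asthma,grp_ecld
c_ecld_asthma_01,c_ecld_asthma
c_ecld_asthma_02,c_ecld_asthma_01
c_ecld_asthma_03,c_ecld_asthma
c_ecld_asthma_04,c_ecld_asthma_03
c_ecld_asthma_05,c_ecld_asthma_03
c_ecld_asthma_06,c_ecld_asthma
c_ecld_asthma_07,c_ecld_asthma_04
c_ecld_copd,grp_ecld
c_ecld_copd_01,c_ecld_copd
c_ecld_copd_02,c_ecld_copd_01
c_ecld_copd_03,c_ecld_copd_01
c_ecld_copd_04,c_ecld_copd_02
c_ecld_copd_05,c_ecld_copd_02
c_ecld_bronchiectasis,grp_ecld
c_ecld_bronchiectasis_01,c_ecld_bronchiectasis
c_ecld_bronchiectasis_02,c_ecld_bronchiectasis
c_ecld_bronchiectasis_03,c_ecld_bronchiectasis
c_ecld_bronchiectasis_04,c_ecld_bronchiectasis_02
c_lrti_pneumonia,grp_lrti
c_lrti_pneumonia_01,c_lrti_pneumonia
c_lrti_pneumonia_02,c_lrti_pneumonia_01
c_lrti_pneumonia_03,c_lrti_pneumonia_01
c_lrti_pneumonia_04,c_lrti_pneumonia_03
c_lrti_acute_bronchitis,grp_lrti
c_lrti_acute_bronchitis_01,c_lrti_acute_bronchitis
c_lrti_acute_bronchitis_02,c_lrti_acute_bronchitis_01
c_lrti_acute_bronchitis_03,c_lrti_acute_bronchitis
c_lrti_acute_bronchitis_04,c_lrti_acute_bronchitis_01
c_lrti_acute_bronchitis_05,c_lrti_acute_bronchitis_02
c_lrti_acute_bronchitis_06,c_lrti_acute_bronchitis_05
c_lrti_acute_bronchitis_07,c_lrti_acute_bronchitis_01
c_lrti_bronchiolitis,grp_lrti
c_lrti_bronchiolitis_01,c_lrti_bronchiolitis
c_lrti_bronchiolitis_02,c_lrti_bronchiolitis_01
c_lrti_bronchiolitis_03,c_lrti_bronchiolitis_01
c_lrti_bronchiolitis_04,c_lrti_bronchiolitis_01
c_lrti_bronchiolitis_05,c_lrti_bronchiolitis_04
c_lrti_bronchiolitis_06,c_lrti_bronchiolitis_03
c_lrti_bronchiolitis_07,c_lrti_bronchiolitis_04
c_lrti_nos,grp_lrti
c_lrti_nos_01,c_lrti_nos
c_lrti_nos_02,c_lrti_nos_01
c_lrti_nos_03,c_lrti_nos_01
c_lrti_nos_04,c_lrti_nos_02
c_lrti_nos_05,c_lrti_nos
c_lrti_nos_06,c_lrti_nos_04
c_lrti_nos_07,c_lrti_nos_01
c_urti_sinusitis,grp_urti
c_urti_sinusitis_01,c_urti_sinusitis
c_urti_sinusitis_02,c_urti_sinusitis_01
c_urti_sinusitis_03,c_urti_sinusitis_01
c_urti_sinusitis_04,c_urti_sinusitis_03
c_urti_sinusitis_05,c_urti_sinusitis_02
c_urti_pharyngitis,grp_urti
c_urti_pharyngitis_01,c_urti_pharyngitis
c_urti_pharyngitis_02,c_urti_pharyngitis_01
c_urti_pharyngitis_03,c_urti_pharyngitis_02
c_urti_pharyngitis_04,c_urti_pharyngitis_01
c_urti_pharyngitis_05,c_urti_pharyngitis_01
c_urti_laryngitis,grp_urti
c_urti_laryngitis_01,c_urti_laryngitis
c_urti_laryngitis_02,c_urti_laryngitis
c_urti_laryngitis_03,c_urti_laryngitis
c_urti_laryngitis_04,c_urti_laryngitis
c_urti_laryngitis_05,c_urti_laryngitis_03
c_urti_otitis_media,grp_urti
c_urti_otitis_media_01,c_urti_otitis_media
c_urti_otitis_media_02,c_urti_otitis_media
c_urti_otitis_media_03,c_urti_otitis_media
c_urti_otitis_media_04,c_urti_otitis_media_03
c_urti_coryza,grp_urti
c_urti_coryza_01,c_urti_coryza
c_urti_coryza_02,c_urti_coryza
c_urti_coryza_03,c_urti_coryza_02
c_urti_coryza_04,c_urti_coryza
c_urti_coryza_05,c_urti_coryza_04
c_urti_coryza_06,c_urti_coryza_03
c_urti_coryza_07,c_urti_coryza_05
c_urti_nos,grp_urti
c_urti_nos_01,c_urti_nos
c_urti_nos_02,c_urti_nos_01
c_urti_nos_03,c_urti_nos_01
c_urti_nos_04,c_urti_nos_01
c_arinos_unspecified,grp_arinos
c_arinos_unspecified_01,c_arinos_unspecified
c_arinos_unspecified_02,c_arinos_unspecified_01
c_arinos_unspecified_03,c_arinos_unspecified
c_arinos_unspecified_04,c_arinos_unspecified_01
c_arinos_unspecified_05,c_arinos_unspecified_04
c_arinos_unspecified_06,c_arinos_unspecified_03
c_arinos_unspecified_07,c_arinos_unspecified
c_arinos_suspected_covid,grp_arinos
c_arinos_suspected_covid_01,c_arinos_suspected_covid
c_arinos_suspected_covid_02,c_arinos_suspected_covid_01
c_arinos_suspected_covid_03,c_arinos_suspected_covid_01
c_arinos_suspected_covid_04,c_arinos_suspected_covid_02
c_arinos_suspected_covid_05,c_arinos_suspected_covid_04
c_arinos_suspected_covid_06,c_arinos_suspected_covid_04
c_arinos_suspected_covid_07,c_arinos_suspected_covid_05
c_ecld_bronchiectasis_04,c_ecld_copd
c_ecld_copd_05,c_ecld_bronchiectasis
c_lrti_pneumonia_01,c_lrti_acute_bronchitis
c_lrti_pneumonia_03,c_lrti_bronchiolitis
c_urti_sinusitis_05,c_urti_laryngitis
c_urti_nos_01,c_urti_sinusitis
c_arinos_suspected_covid_01,c_arinos_unspecified
c_arinos_unspecified_02,c_arinos_suspected_covid
x_copd_chronic,c_ecld_copd
x_copd_chronic_01,x_copd_chronic
x_copd_chronic_02,x_copd_chronic
x_bronchitis_recurrent,c_lrti_acute_bronchitis
x_bronchitis_recurrent_01,x_bronchitis_recurrent
x_bronchitis_recurrent_02,x_bronchitis_recurrent
x_sinusitis_chronic,c_urti_sinusitis
x_sinusitis_chronic_01,x_sinusitis_chronic
x_sinusitis_chronic_02,x_sinusitis_chronic
decoy_root,resp_cond
d_copd_nos,decoy_root
d_chronic_bronchitis,decoy_root
d_asthma_chronic,decoy_root
d_pulmonary_fibrosis,decoy_root
d_emphysema,decoy_root
d_allergic_rhinitis,decoy_root
d_hay_fever,decoy_root
d_vasomotor_rhinitis,decoy_root
d_nasal_polyp,decoy_root
d_chronic_cough,decoy_root
d_recurrent_tonsillitis,decoy_root
d_recurrent_sinusitis_hx,decoy_root
d_recurrent_chest_infection_hx,decoy_root
d_post_viral_cough,decoy_root
d_bronchiectasis_stable,decoy_root
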