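code
c_arinos_suspected_covid
c_arinos_suspected_covid_01
c_arinos_suspected_covid_02
c_arinos_suspected_covid_03
c_arinos_suspected_covid_04
c_arinos_suspected_covid_06
c_arinos_suspected_covid_07
c_arinos_unspecified
c_arinos_unspecified_01
c_arinos_unspecified_02
c_arinos_unspecified_03
c_arinos_unspecified_04
c_arinos_unspecified_06
c_arinos_unspecified_07
c_ecld_asthma
c_ecld_asthma_01
c_ecld_asthma_02
c_ecld_asthma_03
c_ecld_asthma_04
c_ecld_asthma_05
c_ecld_asthma_06
c_ecld_asthma_07
c_ecld_bronchiectasis_01
c_ecld_bronchiectasis_02
c_ecld_bronchiectasis_03
c_ecld_copd
c_ecld_copd_01
c_ecld_copd_03
c_ecld_copd_04
c_ecld_copd_05
c_ili
c_ili_02
c_ili_03
c_ili_04
c_lrti_acute_bronchitis
c_lrti_acute_bronchitis_03
c_lrti_acute_bronchitis_04
c_lrti_acute_bronchitis_05
c_lrti_acute_bronchitis_07
c_lrti_bronchiolitis
c_lrti_bronchiolitis_01
c_lrti_bronchiolitis_02
c_lrti_bronchiolitis_03
c_lrti_bronchiolitis_04
c_lrti_bronchiolitis_05
c_lrti_bronchiolitis_06
c_lrti_bronchiolitis_07
c_lrti_nos_01
c_lrti_nos_02
c_lrti_nos_03
c_lrti_nos_04
c_lrti_nos_07
c_lrti_pneumonia
c_lrti_pneumonia_01
c_lrti_pneumonia_02
c_lrti_pneumonia_03
c_lrti_pneumonia_04
c_urti_coryza
c_urti_coryza_01
c_urti_coryza_02
c_urti_coryza_03
c_urti_coryza_04
c_urti_coryza_05
c_urti_coryza_06
c_urti_coryza_07
c_urti_laryngitis
c_urti_laryngitis_01
c_urti_laryngitis_02
c_urti_laryngitis_04
c_urti_laryngitis_05
c_urti_nos
c_urti_nos_01
c_urti_nos_02
c_urti_nos_03
c_urti_nos_04
c_urti_otitis_media
c_urti_otitis_media_01
c_urti_otitis_media_02
c_urti_otitis_media_03
c_urti_otitis_media_04
c_urti_pharyngitis
c_urti_pharyngitis_01
c_urti_pharyngitis_02
c_urti_pharyngitis_04
c_urti_pharyngitis_05
c_urti_sinusitis
c_urti_sinusitis_01
c_urti_sinusitis_02
c_urti_sinusitis_03
d_allergic_rhinitis
d_asthma_chronic
d_bronchiectasis_stable
d_chronic_bronchitis
d_chronic_cough
d_copd_nos
d_emphysema
d_hay_fever
d_nasal_polyp
d_post_viral_cough
d_pulmonary_fibrosis
d_recurrent_chest_infection_hx
d_recurrent_sinusitis_hx
d_recurrent_tonsillitis
d_vasomotor_rhinitis
x_bronchitis_recurrent
x_bronchitis_recurrent_01
x_bronchitis_recurrent_02
x_copd_chronic
x_copd_chronic_01
x_copd_chronic_02
x_sinusitis_chronic
x_sinusitis_chronic_01
x_sinusitis_chronic_02
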