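code,label
resp_cond,Respiratory condition
grp_ili,Group concept: ILI
grp_ecld,Group concept: ECLD
grp_lrti,Group concept: LRTI
grp_urti,Group concept: URTI
grp_arinos,Group concept: ARI-NOS
c_ili,Anchor: ili
c_ili_01,"ili, presentation 1"
c_ili_02,"ili, presentation 2"
c_ili_03,"ili, presentation 3"
c_ili_04,"ili, presentation 4"
c_ecld_asthma,Anchor: ecld asthma
c_ecld_asthma_01,"ecld asthma, presentation 1"
c_ecld_asthma_02,"ecld asthma, presentation 2"
c_ecld_asthma_03,"ecld asthma, presentation 3"
c_ecld_asthma_04,"ecld asthma, presentation 4"
c_ecld_asthma_05,"ecld asthma, presentation 5"
c_ecld_asthma_06,"ecld asthma, presentation 6"
c_ecld_asthma_07,"ecld asthma, presentation 7"
c_ecld_copd,Anchor: ecld copd
c_ecld_copd_01,"ecld copd, presentation 1"
c_ecld_copd_02,"ecld copd, presentation 2"
c_ecld_copd_03,"ecld copd, presentation 3"
c_ecld_copd_04,"ecld copd, presentation 4"
c_ecld_copd_05,"ecld copd, presentation 5"
c_ecld_bronchiectasis,Anchor: ecld bronchiectasis
c_ecld_bronchiectasis_01,"ecld bronchiectasis, presentation 1"
c_ecld_bronchiectasis_02,"ecld bronchiectasis, presentation 2"
c_ecld_bronchiectasis_03,"ecld bronchiectasis, presentation 3"
c_ecld_bronchiectasis_04,"ecld bronchiectasis, presentation 4"
c_lrti_pneumonia,Anchor: lrti pneumonia
c_lrti_pneumonia_01,"lrti pneumonia, presentation 1"
c_lrti_pneumonia_02,"lrti pneumonia, presentation 2"
c_lrti_pneumonia_03,"lrti pneumonia, presentation 3"
c_lrti_pneumonia_04,"lrti pneumonia, presentation 4"
c_lrti_acute_bronchitis,Anchor: lrti acute bronchitis
c_lrti_acute_bronchitis_01,"lrti acute bronchitis, presentation 1"
c_lrti_acute_bronchitis_02,"lrti acute bronchitis, presentation 2"
c_lrti_acute_bronchitis_03,"lrti acute bronchitis, presentation 3"
c_lrti_acute_bronchitis_04,"lrti acute bronchitis, presentation 4"
c_lrti_acute_bronchitis_05,"lrti acute bronchitis, presentation 5"
c_lrti_acute_bronchitis_06,"lrti acute bronchitis, presentation 6"
c_lrti_acute_bronchitis_07,"lrti acute bronchitis, presentation 7"
c_lrti_bronchiolitis,Anchor: lrti bronchiolitis
c_lrti_bronchiolitis_01,"lrti bronchiolitis, presentation 1"
c_lrti_bronchiolitis_02,"lrti bronchiolitis, presentation 2"
c_lrti_bronchiolitis_03,"lrti bronchiolitis, presentation 3"
c_lrti_bronchiolitis_04,"lrti bronchiolitis, presentation 4"
c_lrti_bronchiolitis_05,"lrti bronchiolitis, presentation 5"
c_lrti_bronchiolitis_06,"lrti bronchiolitis, presentation 6"
c_lrti_bronchiolitis_07,"lrti bronchiolitis, presentation 7"
c_lrti_nos,Anchor: lrti nos
c_lrti_nos_01,"lrti nos, presentation 1"
c_lrti_nos_02,"lrti nos, presentation 2"
c_lrti_nos_03,"lrti nos, presentation 3"
c_lrti_nos_04,"lrti nos, presentation 4"
c_lrti_nos_05,"lrti nos, presentation 5"
c_lrti_nos_06,"lrti nos, presentation 6"
c_lrti_nos_07,"lrti nos, presentation 7"
c_urti_sinusitis,Anchor: urti sinusitis
c_urti_sinusitis_01,"urti sinusitis, presentation 1"
c_urti_sinusitis_02,"urti sinusitis, presentation 2"
c_urti_sinusitis_03,"urti sinusitis, presentation 3"
c_urti_sinusitis_04,"urti sinusitis, presentation 4"
c_urti_sinusitis_05,"urti sinusitis, presentation 5"
c_urti_pharyngitis,Anchor: urti pharyngitis
c_urti_pharyngitis_01,"urti pharyngitis, presentation 1"
c_urti_pharyngitis_02,"urti pharyngitis, presentation 2"
c_urti_pharyngitis_03,"urti pharyngitis, presentation 3"
c_urti_pharyngitis_04,"urti pharyngitis, presentation 4"
c_urti_pharyngitis_05,"urti pharyngitis, presentation 5"
c_urti_laryngitis,Anchor: urti laryngitis
c_urti_laryngitis_01,"urti laryngitis, presentation 1"
c_urti_laryngitis_02,"urti laryngitis, presentation 2"
c_urti_laryngitis_03,"urti laryngitis, presentation 3"
c_urti_laryngitis_04,"urti laryngitis, presentation 4"
c_urti_laryngitis_05,"urti laryngitis, presentation 5"
c_urti_otitis_media,Anchor: urti otitis media
c_urti_otitis_media_01,"urti otitis media, presentation 1"
c_urti_otitis_media_02,"urti otitis media, presentation 2"
c_urti_otitis_media_03,"urti otitis media, presentation 3"
c_urti_otitis_media_04,"urti otitis media, presentation 4"
c_urti_coryza,Anchor: urti coryza
c_urti_coryza_01,"urti coryza, presentation 1"
c_urti_coryza_02,"urti coryza, presentation 2"
c_urti_coryza_03,"urti coryza, presentation 3"
c_urti_coryza_04,"urti coryza, presentation 4"
c_urti_coryza_05,"urti coryza, presentation 5"
c_urti_coryza_06,"urti coryza, presentation 6"
c_urti_coryza_07,"urti coryza, presentation 7"
c_urti_nos,Anchor: urti nos
c_urti_nos_01,"urti nos, presentation 1"
c_urti_nos_02,"urti nos, presentation 2"
c_urti_nos_03,"urti nos, presentation 3"
c_urti_nos_04,"urti nos, presentation 4"
c_arinos_unspecified,Anchor: arinos unspecified
c_arinos_unspecified_01,"arinos unspecified, presentation 1"
c_arinos_unspecified_02,"arinos unspecified, presentation 2"
c_arinos_unspecified_03,"arinos unspecified, presentation 3"
c_arinos_unspecified_04,"arinos unspecified, presentation 4"
c_arinos_unspecified_05,"arinos unspecified, presentation 5"
c_arinos_unspecified_06,"arinos unspecified, presentation 6"
c_arinos_unspecified_07,"arinos unspecified, presentation 7"
c_arinos_suspected_covid,Anchor: arinos suspected covid
c_arinos_suspected_covid_01,"arinos suspected covid, presentation 1"
c_arinos_suspected_covid_02,"arinos suspected covid, presentation 2"
c_arinos_suspected_covid_03,"arinos suspected covid, presentation 3"
c_arinos_suspected_covid_04,"arinos suspected covid, presentation 4"
c_arinos_suspected_covid_05,"arinos suspected covid, presentation 5"
c_arinos_suspected_covid_06,"arinos suspected covid, presentation 6"
c_arinos_suspected_covid_07,"arinos suspected covid, presentation 7"
x_copd_chronic,copd chronic
x_copd_chronic_01,"copd chronic, form 1"
x_copd_chronic_02,"copd chronic, form 2"
x_bronchitis_recurrent,bronchitis recurrent
x_bronchitis_recurrent_01,"bronchitis recurrent, form 1"
x_bronchitis_recurrent_02,"bronchitis recurrent, form 2"
x_sinusitis_chronic,sinusitis chronic
x_sinusitis_chronic_01,"sinusitis chronic, form 1"
x_sinusitis_chronic_02,"sinusitis chronic, form 2"
decoy_root,Non-acute respiratory concepts
d_copd_nos,copd nos
d_chronic_bronchitis,chronic bronchitis
d_asthma_chronic,asthma chronic
d_pulmonary_fibrosis,pulmonary fibrosis
d_emphysema,emphysema
d_allergic_rhinitis,allergic rhinitis
d_hay_fever,hay fever
d_vasomotor_rhinitis,vasomotor rhinitis
d_nasal_polyp,nasal polyp
d_chronic_cough,chronic cough
d_recurrent_tonsillitis,recurrent tonsillitis
d_recurrent_sinusitis_hx,recurrent sinusitis hx
d_recurrent_chest_infection_hx,recurrent chest infection hx
d_post_viral_cough,post viral cough
d_bronchiectasis_stable,bronchiectasis stable
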