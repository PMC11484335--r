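{
  "level1_size": 105,
  "level2_sizes": {
    "ILI": 5,
    "ECLD": 19,
    "LRTI": 29,
    "URTI": 36,
    "ARI-NOS": 16
  },
  "level3_sizes": {
    "ili": 5,
    "ecld_asthma": 8,
    "ecld_copd": 7,
    "ecld_bronchiectasis": 6,
    "lrti_pneumonia": 5,
    "lrti_acute_bronchitis": 12,
    "lrti_bronchiolitis": 10,
    "lrti_nos": 8,
    "urti_sinusitis": 10,
    "urti_pharyngitis": 6,
    "urti_laryngitis": 7,
    "urti_otitis_media": 5,
    "urti_coryza": 8,
    "urti_nos": 5,
    "arinos_unspecified": 15,
    "arinos_suspected_covid": 9
  }
}
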