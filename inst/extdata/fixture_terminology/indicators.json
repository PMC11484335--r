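{
  "level1": "ARI",
  "level2": ["ILI", "ECLD", "LRTI", "URTI", "ARI-NOS"],
  "level3": [
    {
      "id": "ili",
      "level2_parent": "ILI",
      "ecl": "<<c_ili"
    },
    {
      "id": "ecld_asthma",
      "level2_parent": "ECLD",
      "ecl": "<<c_ecld_asthma"
    },
    {
      "id": "ecld_copd",
      "level2_parent": "ECLD",
      "ecl": "<<c_ecld_copd MINUS <<x_copd_chronic"
    },
    {
      "id": "ecld_bronchiectasis",
      "level2_parent": "ECLD",
      "ecl": "<<c_ecld_bronchiectasis"
    },
    {
      "id": "lrti_pneumonia",
      "level2_parent": "LRTI",
      "ecl": "<<c_lrti_pneumonia"
    },
    {
      "id": "lrti_acute_bronchitis",
      "level2_parent": "LRTI",
      "ecl": "<<c_lrti_acute_bronchitis MINUS <<x_bronchitis_recurrent"
    },
    {
      "id": "lrti_bronchiolitis",
      "level2_parent": "LRTI",
      "ecl": "<<c_lrti_bronchiolitis"
    },
    {
      "id": "lrti_nos",
      "level2_parent": "LRTI",
      "ecl": "<<c_lrti_nos"
    },
    {
      "id": "urti_sinusitis",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_sinusitis MINUS <<x_sinusitis_chronic"
    },
    {
      "id": "urti_pharyngitis",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_pharyngitis"
    },
    {
      "id": "urti_laryngitis",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_laryngitis"
    },
    {
      "id": "urti_otitis_media",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_otitis_media"
    },
    {
      "id": "urti_coryza",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_coryza"
    },
    {
      "id": "urti_nos",
      "level2_parent": "URTI",
      "ecl": "<<c_urti_nos"
    },
    {
      "id": "arinos_unspecified",
      "level2_parent": "ARI-NOS",
      "ecl": "(c_arinos_unspecified OR <c_arinos_unspecified)"
    },
    {
      "id": "arinos_suspected_covid",
      "level2_parent": "ARI-NOS",
      "ecl": "<<c_arinos_suspected_covid"
    }
  ]
}
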