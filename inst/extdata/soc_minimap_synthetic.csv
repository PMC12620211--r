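"pt","soc"
"Abscess","Infections and infestations"
"Abscess limb","Infections and infestations"
"Acne pustular","Infections and infestations"
"Appendicitis","Infections and infestations"
"Arthritis bacterial","Infections and infestations"
"Arthritis infective","Infections and infestations"
"Bacteremia","Infections and infestations"
"Bacterial infection","Infections and infestations"
"Beta hemolytic streptococcal infection","Infections and infestations"
"Body tinea","Infections and infestations"
"Cellulitis","Infections and infestations"
"Cystitis","Infections and infestations"
"Dengue fever","Infections and infestations"
"Dermatitis infected","Infections and infestations"
"Device-related infection","Infections and infestations"
"Diverticulitis","Infections and infestations"
"Eczema herpeticum","Infections and infestations"
"Eczema infected","Infections and infestations"
"Epstein-Barr virus infection","Infections and infestations"
"Erysipelas","Infections and infestations"
"Folliculitis","Infections and infestations"
"Gastric infection","Infections and infestations"
"Gastroenteritis","Infections and infestations"
"Hepatitis e","Infections and infestations"
"Herpes ophthalmic","Infections and infestations"
"Herpes simplex","Infections and infestations"
"Herpes simplex reactivation","Infections and infestations"
"Herpes virus infection","Infections and infestations"
"Herpes zoster","Infections and infestations"
"Herpes zoster cutaneous disseminated","Infections and infestations"
"Herpes zoster disseminated","Infections and infestations"
"Impetigo","Infections and infestations"
"Influenza","Infections and infestations"
"Latent tuberculosis","Infections and infestations"
"Lower respiratory tract infection","Infections and infestations"
"Meningitis","Infections and infestations"
"Necrotizing fasciitis","Infections and infestations"
"Ophthalmic herpes simplex","Infections and infestations"
"Ophthalmic herpes zoster","Infections and infestations"
"Oral pustule","Infections and infestations"
"Osteomyelitis","Infections and infestations"
"Otitis externa","Infections and infestations"
"Peritonsillar abscess","Infections and infestations"
"Pneumocystis jirovecii pneumonia","Infections and infestations"
"Pneumonia","Infections and infestations"
"Post-procedural infection","Infections and infestations"
"Pulmonary tuberculosis","Infections and infestations"
"Purulence","Infections and infestations"
"Pyelonephritis","Infections and infestations"
"Respiratory syncytial virus infection","Infections and infestations"
"Sepsis","Infections and infestations"
"Septic shock","Infections and infestations"
"Skin bacterial infection","Infections and infestations"
"Skin infection","Infections and infestations"
"Staphylococcal bacteremia","Infections and infestations"
"Staphylococcal infection","Infections and infestations"
"Staphylococcal sepsis","Infections and infestations"
"Staphylococcal skin infection","Infections and infestations"
"Superinfection bacterial","Infections and infestations"
"Tonsillitis","Infections and infestations"
"Tuberculosis","Infections and infestations"
"Upper respiratory tract infection","Infections and infestations"
"Urinary tract infection","Infections and infestations"
"Urosepsis","Infections and infestations"
"Vaginal infection","Infections and infestations"
"Varicella","Infections and infestations"
"Wound infection","Infections and infestations"
"Wound infection bacterial","Infections and infestations"
"Nasopharyngitis","Infections and infestations"
"Sinusitis","Infections and infestations"
"Bronchitis","Infections and infestations"
"Oral herpes","Infections and infestations"
"Conjunctivitis","Infections and infestations"
"Fungal infection","Infections and infestations"
"Candida infection","Infections and infestations"
"Ear infection","Infections and infestations"
"Localised infection","Infections and infestations"
"Oral candidiasis","Infections and infestations"
"Pruritus","Skin and subcutaneous tissue disorders"
"Dermatitis atopic","Skin and subcutaneous tissue disorders"
"Rash","Skin and subcutaneous tissue disorders"
"Headache","Nervous system disorders"
"Nausea","Gastrointestinal disorders"
"Fatigue","General disorders and administration site conditions"
"Diarrhoea","Gastrointestinal disorders"
"Arthralgia","Musculoskeletal and connective tissue disorders"
"Dizziness","Nervous system disorders"
"Vomiting","Gastrointestinal disorders"
"Alopecia","Skin and subcutaneous tissue disorders"
"Insomnia","Psychiatric disorders"
"Pyrexia","General disorders and administration site conditions"
"Cough","Respiratory, thoracic and mediastinal disorders"
"Dyspnoea","Respiratory, thoracic and mediastinal disorders"
"Hypertension","Vascular disorders"
"Anxiety","Psychiatric disorders"
"Pain","General disorders and administration site conditions"
"Weight increased","Investigations"
"Drug ineffective","General disorders and administration site conditions"
"Abdominal pain","Gastrointestinal disorders"
"Asthenia","General disorders and administration site conditions"
"Pruritus generalised","Skin and subcutaneous tissue disorders"
"Skin exfoliation","Skin and subcutaneous tissue disorders"
"Erythema","Skin and subcutaneous tissue disorders"
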