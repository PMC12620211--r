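drug,pt,n,ror,ror_lo,ror_hi,prr,chi2,ebgm,ebgm05,ic,ic025
Abrocitinib,Herpes zoster,26,6.4,4.3,9.53,6.36,110.97,6.06,4.34,2.6,2.03
Abrocitinib,Eczema herpeticum,19,21.91,13.36,35.94,21.79,312.99,18.26,12.07,4.19,3.49
Abrocitinib,Cellulitis,15,8.78,5.18,14.88,8.74,95.09,8.15,5.24,3.03,2.28
Abrocitinib,Herpes simplex,7,9.97,4.59,21.66,9.95,51.57,9.19,4.8,3.2,2.13
Abrocitinib,Sepsis,6,4.78,2.11,10.84,4.77,17.15,4.61,2.33,2.21,1.09
Abrocitinib,Skin infection,6,4.19,1.85,9.48,4.18,13.98,4.06,2.05,2.02,0.91
Abrocitinib,Folliculitis,6,16.02,6.79,37.82,16,73.36,14.04,6.84,3.81,2.64
Abrocitinib,Impetigo,5,10.47,4.18,26.25,10.45,38.94,9.61,4.45,3.26,2.03
Abrocitinib,Lower respiratory tract infection,5,10.27,4.1,25.72,10.25,38.1,9.44,4.38,3.24,2
Abrocitinib,Herpes virus infection,5,9.05,3.63,22.56,9.04,32.95,8.41,3.92,3.07,1.84
Abrocitinib,Appendicitis,4,11.24,4.01,31.51,11.22,33.71,10.25,4.33,3.36,1.99
Abrocitinib,Erysipelas,4,23.73,8.03,70.15,23.7,71.15,19.57,7.9,4.29,2.87
Abrocitinib,Ophthalmic herpes simplex,3,18.84,5.52,64.31,18.82,43.02,16.15,5.78,4.01,2.44
Abrocitinib,Septic shock,3,13.34,4.02,44.33,13.33,30.41,11.96,4.38,3.58,2.04
Abrocitinib,Staphylococcal sepsis,3,53.37,13.34,213.49,53.32,102.68,35.88,11.25,5.17,3.46
Abrocitinib,Osteomyelitis,3,11.86,3.6,39.11,11.85,26.82,10.76,3.97,3.43,1.89
Abrocitinib,Superinfection bacterial,3,40.03,10.61,150.95,39.99,82.94,29.36,9.67,4.88,3.21
Abrocitinib,Herpes zoster disseminated,3,53.37,13.34,213.49,53.32,102.68,35.88,11.25,5.17,3.46
Upadacitinib,Herpes zoster,97,7.76,6.24,9.65,7.7,475.31,6.62,5.52,2.73,2.41
Upadacitinib,Pneumonia,85,4.21,3.36,5.27,4.18,186.8,3.88,3.22,1.96,1.63
Upadacitinib,Influenza,68,2.61,2.04,3.33,2.6,62.86,2.5,2.03,1.32,0.96
Upadacitinib,Urinary tract infection,62,3.66,2.82,4.75,3.64,109.18,3.42,2.75,1.78,1.4
Upadacitinib,Eczema herpeticum,44,18.33,12.83,26.19,18.26,493.85,12.87,9.55,3.69,3.19
Upadacitinib,Sepsis,34,10.72,7.34,15.66,10.69,236.05,8.66,6.31,3.11,2.58
Upadacitinib,Staphylococcal infection,33,5.64,3.92,8.13,5.63,110.23,5.06,3.73,2.34,1.81
Upadacitinib,Herpes simplex,27,13.79,8.9,21.35,13.75,238.05,10.51,7.29,3.39,2.78
Upadacitinib,Upper respiratory tract infection,24,3.3,2.18,5.01,3.3,35.51,3.12,2.2,1.64,1.04
Upadacitinib,Cellulitis,23,3.98,2.59,6.11,3.97,46.59,3.71,2.59,1.89,1.27
Upadacitinib,Diverticulitis,19,7.16,4.39,11.66,7.15,85.32,6.22,4.13,2.64,1.94
Upadacitinib,Herpes virus infection,14,7.33,4.14,12.95,7.32,64.62,6.35,3.94,2.67,1.86
Upadacitinib,Folliculitis,14,11.51,6.35,20.86,11.5,104.39,9.17,5.57,3.2,2.37
Upadacitinib,Appendicitis,13,13.09,7,24.49,13.08,109.47,10.12,5.99,3.34,2.47
Upadacitinib,Herpes ophthalmic,12,10.07,5.35,18.96,10.06,78.35,8.25,4.86,3.04,2.16
Upadacitinib,Post-procedural infection,11,11.08,5.68,21.6,11.07,79.02,8.9,5.09,3.15,2.23
Upadacitinib,Ophthalmic herpes zoster,11,24.62,11.62,52.14,24.59,154.55,15.64,8.35,3.97,2.98
Upadacitinib,Cystitis,11,4.48,2.4,8.35,4.47,26.69,4.12,2.45,2.04,1.17
Upadacitinib,Osteomyelitis,9,13.94,6.53,29.76,13.93,80.25,10.61,5.62,3.41,2.37
Upadacitinib,Bacterial infection,9,4.47,2.25,8.91,4.47,21.84,4.12,2.32,2.04,1.08
Upadacitinib,Ophthalmic herpes simplex,9,27.88,11.92,65.25,27.86,137.73,16.87,8.28,4.08,2.98
Upadacitinib,Respiratory syncytial virus infection,8,4.54,2.18,9.43,4.53,19.81,4.18,2.27,2.06,1.05
Upadacitinib,Arthritis infective,7,20.13,8.12,49.9,20.12,84.81,13.75,6.43,3.78,2.59
Upadacitinib,Bacteremia,7,21.68,8.65,54.36,21.67,89.71,14.44,6.69,3.85,2.65
Upadacitinib,Meningitis,7,20.13,8.12,49.9,20.12,84.81,13.75,6.43,3.78,2.59
Upadacitinib,Erysipelas,6,12.72,5.08,31.84,12.71,49.19,9.9,4.59,3.31,2.08
Upadacitinib,Latent tuberculosis,6,24.16,8.78,66.49,24.15,83.21,15.47,6.63,3.95,2.65
Upadacitinib,Abscess,6,4.47,1.92,10.4,4.47,14.56,4.12,2.04,2.04,0.89
Upadacitinib,Gastric infection,6,16.11,6.25,41.52,16.1,60.69,11.78,5.34,3.56,2.31
Upadacitinib,Herpes zoster disseminated,6,60.4,17.04,214.07,60.37,140.12,24.75,8.58,4.63,3.23
Upadacitinib,Gastroenteritis,6,12.72,5.08,31.84,12.71,49.19,9.9,4.59,3.31,2.08
Upadacitinib,Herpes zoster cutaneous disseminated,5,100.66,19.53,518.89,100.61,140.89,29.46,7.47,4.88,3.32
Upadacitinib,Wound infection,5,9.59,3.61,25.43,9.58,31.04,7.93,3.51,2.99,1.69
Upadacitinib,Staphylococcal skin infection,5,12.58,4.61,34.35,12.58,40.6,9.82,4.24,3.3,1.97
Upadacitinib,Skin bacterial infection,5,15.49,5.52,43.45,15.48,48.91,11.46,4.83,3.52,2.17
Upadacitinib,Staphylococcal sepsis,4,26.84,7.57,95.12,26.83,59.68,16.5,5.72,4.04,2.49
Upadacitinib,Device-related infection,4,13.42,4.33,41.62,13.41,34.47,10.31,4,3.37,1.9
Upadacitinib,Tuberculosis,4,5.55,1.95,15.8,5.55,13.12,5,2.08,2.32,0.94
Upadacitinib,Pulmonary tuberculosis,4,20.13,6.06,66.86,20.12,48.46,13.75,5.04,3.78,2.26
Upadacitinib,Varicella,4,7.67,2.63,22.34,7.67,19.48,6.6,2.7,2.72,1.31
Upadacitinib,Arthritis bacterial,4,14.64,4.66,45.98,14.63,37.26,11,4.22,3.46,1.98
Upadacitinib,Abscess limb,4,9.47,3.19,28.16,9.47,24.53,7.86,3.16,2.97,1.54
Upadacitinib,Otitis externa,4,17.89,5.51,58.11,17.89,44.15,12.69,4.74,3.67,2.16
Upadacitinib,Vaginal infection,4,8.95,3.03,26.44,8.94,23.09,7.5,3.03,2.91,1.48
Upadacitinib,Septic shock,4,6.44,2.24,18.51,6.44,15.84,5.69,2.35,2.51,1.11
Upadacitinib,Urosepsis,4,23.01,6.73,78.6,23,53.56,15,5.36,3.91,2.37
Upadacitinib,Beta hemolytic streptococcal infection,4,53.68,12.01,239.88,53.66,88.59,23.57,6.73,4.56,2.91
Upadacitinib,Necrotizing fasciitis,4,40.26,10.07,161,40.24,76.54,20.62,6.47,4.37,2.76
Upadacitinib,Tonsillitis,4,5.75,2.02,16.4,5.75,13.73,5.16,2.15,2.37,0.98
Upadacitinib,Purulence,4,80.52,14.75,439.66,80.49,104.67,27.5,6.64,4.78,3.09
Upadacitinib,Pyelonephritis,3,7.55,2.2,25.91,7.55,14.35,6.51,2.32,2.7,1.12
Upadacitinib,Pneumocystis jirovecii pneumonia,3,15.1,4,56.91,15.09,28.71,11.25,3.71,3.49,1.83
Upadacitinib,Dermatitis infected,3,10.06,2.84,35.67,10.06,19.59,8.25,2.86,3.04,1.43
Upadacitinib,Peritonsillar abscess,3,24.15,5.77,101.08,24.15,41.6,15.47,4.67,3.95,2.22
Upadacitinib,Herpes simplex reactivation,3,120.77,12.56,1161.14,120.73,89.06,30.93,4.66,4.95,3.02
Upadacitinib,Hepatitis e,3,60.38,10.09,361.42,60.37,70.06,24.75,5.54,4.63,2.77
Upadacitinib,Oral pustule,3,120.77,12.56,1161.14,120.73,89.06,30.93,4.66,4.95,3.02
Upadacitinib,Dengue fever,3,60.38,10.09,361.42,60.37,70.06,24.75,5.54,4.63,2.77
Upadacitinib,Acne pustular,3,15.1,4,56.91,15.09,28.71,11.25,3.71,3.49,1.83
Upadacitinib,Wound infection bacterial,3,120.77,12.56,1161.14,120.73,89.06,30.93,4.66,4.95,3.02
Upadacitinib,Body tinea,3,12.08,3.32,43.89,12.07,23.44,9.52,3.23,3.25,1.61
Upadacitinib,Epstein-Barr virus infection,3,24.15,5.77,101.08,24.15,41.6,15.47,4.67,3.95,2.22
Upadacitinib,Staphylococcal bacteremia,3,6.36,1.88,21.48,6.35,11.69,5.62,2.03,2.49,0.93
Upadacitinib,Eczema infected,3,7.1,2.08,24.24,7.1,13.37,6.19,2.21,2.63,1.05
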