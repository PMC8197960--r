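city,AIDS,Cirrhosis,COPD,Lung c.,Diabetes,IHD,Dementia,Ictus,Stomach c.,Suicides,Traffic inj.,Bladder c.,Colorectal c.,Haematological c.,Prostate c.,Mean
Alicante,0.52,0.29,0.25,0.14,0.15,0.12,0.10,0.12,0.13,0.26,0.10,0.15,0.02,0.06,0.03,0.16
Almería,0.69,0.40,0.22,0.21,0.35,0.18,0.10,0.13,0.19,0.14,0.17,0.15,0.16,0.11,0.05,0.22
Avilés,0.20,0.30,0.27,0.14,0.17,0.10,0.21,0.15,0.11,0.14,0.07,0.20,0.06,0.15,0.22,0.16
Barcelona,0.48,0.25,0.30,0.14,0.17,0.08,0.21,0.10,0.19,0.13,0.10,0.11,0.11,0.07,0.10,0.17
Bilbao,0.65,0.26,0.31,0.18,0.17,0.12,0.15,0.11,0.17,0.18,0.04,0.08,0.10,0.08,0.09,0.18
Cádiz,0.52,0.25,0.22,0.19,0.10,0.17,0.08,0.13,0.07,0.04,0.20,0.04,0.09,0.17,0.09,0.16
Cartagena,0.46,0.29,0.25,0.20,0.13,0.18,0.17,0.20,0.12,0.11,0.09,0.19,0.14,0.14,0.11,0.19
Castellón,0.32,0.18,0.14,0.09,0.05,0.08,0.04,0.08,0.12,0.12,0.09,0.07,0.05,0.08,0.05,0.10
Córdoba,0.84,0.31,0.25,0.18,0.21,0.18,0.16,0.17,0.13,0.11,0.09,0.18,0.09,0.11,0.16,0.21
Gijón,0.19,0.19,0.19,0.13,0.08,0.11,0.08,0.08,0.10,0.06,0.07,0.07,0.08,0.06,0.05,0.10
Granada,0.70,0.35,0.34,0.19,0.18,0.24,0.13,0.18,0.18,0.21,0.21,0.22,0.21,0.07,0.14,0.24
Huelva,0.68,0.32,0.39,0.25,0.23,0.18,0.27,0.25,0.13,0.11,0.15,0.18,0.19,0.15,0.17,0.24
Jaén,0.34,0.26,0.21,0.12,0.06,0.15,0.06,0.19,0.13,0.20,0.07,0.08,0.07,0.12,0.09,0.14
Madrid,0.61,0.31,0.23,0.16,0.15,0.12,0.16,0.13,0.15,0.12,0.10,0.09,0.08,0.05,0.09,0.17
Málaga,0.57,0.23,0.25,0.17,0.21,0.16,0.15,0.12,0.09,0.09,0.16,0.11,0.07,0.04,0.09,0.17
Murcia,0.37,0.29,0.25,0.18,0.12,0.10,0.16,0.15,0.12,0.08,0.15,0.06,0.05,0.05,0.12,0.15
Oviedo,0.35,0.20,0.20,0.17,0.13,0.11,0.09,0.15,0.17,0.11,0.05,0.17,0.11,0.07,0.03,0.14
Palma de Mallorca,0.35,0.17,0.29,0.13,0.19,0.15,0.25,0.12,0.15,0.17,0.09,0.10,0.05,0.06,0.08,0.16
Palmas Gran Canaria,0.40,0.34,0.32,0.21,0.20,0.18,0.06,0.18,0.24,0.18,0.24,0.14,0.07,0.09,0.07,0.20
Pamplona,0.37,0.16,0.22,0.14,0.15,0.18,0.23,0.11,0.08,0.04,0.07,0.12,0.06,0.14,0.06,0.14
San Sebastián,0.35,0.25,0.21,0.14,0.15,0.12,0.18,0.11,0.09,0.05,0.07,0.05,0.07,0.10,0.08,0.13
Santa Cruz Tenerife,0.50,0.24,0.34,0.21,0.21,0.15,0.12,0.08,0.14,0.08,0.19,0.09,0.09,0.08,0.18,0.18
Santander,0.17,0.17,0.27,0.12,0.12,0.12,0.15,0.15,0.09,0.10,0.07,0.07,0.12,0.07,0.04,0.12
Sevilla,0.74,0.39,0.32,0.21,0.16,0.15,0.11,0.17,0.15,0.22,0.20,0.15,0.10,0.06,0.08,0.21
Valencia,0.55,0.22,0.19,0.12,0.11,0.11,0.09,0.10,0.10,0.04,0.12,0.10,0.04,0.07,0.03,0.13
Vitoria,0.56,0.37,0.25,0.14,0.08,0.19,0.15,0.15,0.05,0.20,0.12,0.10,0.11,0.13,0.06,0.18
Mean,0.48,0.27,0.26,0.16,0.16,0.14,0.14,0.14,0.13,0.13,0.12,0.12,0.09,0.09,0.09,
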