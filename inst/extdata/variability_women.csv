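city,Diabetes,Dementia,IHD,COPD,Ictus,Cirrhosis,Stomach c.,Lung c.,Breast c.,Colorectal c.,Haematological c.,Mean
Alicante,0.16,0.21,0.13,0.13,0.10,0.19,0.04,0.06,0.07,0.04,0.05,0.11
Almería,0.19,0.20,0.27,0.08,0.18,0.05,0.08,0.11,0.10,0.14,0.10,0.14
Avilés,0.05,0.24,0.10,0.11,0.22,0.07,0.02,0.05,0.15,0.05,0.06,0.10
Barcelona,0.26,0.24,0.19,0.27,0.15,0.21,0.13,0.20,0.14,0.10,0.10,0.18
Bilbao,0.19,0.23,0.10,0.18,0.08,0.21,0.22,0.16,0.04,0.06,0.03,0.14
Cádiz,0.15,0.10,0.19,0.07,0.11,0.16,0.13,0.08,0.08,0.07,0.14,0.12
Cartagena,0.19,0.18,0.20,0.24,0.23,0.20,0.07,0.05,0.18,0.17,0.11,0.16
Castellón,0.07,0.15,0.10,0.06,0.09,0.05,0.04,0.10,0.02,0.07,0.04,0.07
Córdoba,0.17,0.20,0.21,0.18,0.17,0.12,0.20,0.09,0.10,0.09,0.12,0.15
Gijón,0.17,0.13,0.15,0.13,0.12,0.04,0.11,0.05,0.09,0.06,0.02,0.10
Granada,0.29,0.14,0.20,0.16,0.21,0.26,0.20,0.07,0.09,0.11,0.09,0.17
Huelva,0.26,0.27,0.20,0.18,0.20,0.14,0.07,0.12,0.10,0.12,0.08,0.16
Jaén,0.27,0.17,0.16,0.25,0.12,0.22,0.27,0.07,0.04,0.13,0.09,0.16
Madrid,0.21,0.24,0.15,0.22,0.13,0.12,0.11,0.20,0.08,0.08,0.05,0.14
Málaga,0.22,0.25,0.14,0.11,0.15,0.16,0.11,0.06,0.07,0.09,0.04,0.13
Murcia,0.33,0.24,0.17,0.17,0.19,0.14,0.12,0.11,0.09,0.10,0.11,0.16
Oviedo,0.24,0.10,0.11,0.11,0.09,0.09,0.16,0.06,0.04,0.04,0.04,0.10
Palma de Mallorca,0.34,0.40,0.25,0.23,0.21,0.10,0.15,0.13,0.17,0.12,0.08,0.20
Palmas Gran Canaria,0.31,0.10,0.19,0.22,0.18,0.14,0.18,0.07,0.08,0.09,0.14,0.16
Pamplona,0.21,0.25,0.19,0.21,0.16,0.08,0.05,0.05,0.06,0.12,0.05,0.13
San Sebastián,0.34,0.31,0.17,0.24,0.17,0.19,0.18,0.07,0.07,0.06,0.08,0.17
Santa Cruz Tenerife,0.20,0.08,0.13,0.09,0.09,0.17,0.02,0.10,0.09,0.05,0.05,0.10
Santander,0.19,0.22,0.17,0.17,0.19,0.09,0.05,0.05,0.10,0.08,0.02,0.12
Sevilla,0.27,0.20,0.22,0.20,0.22,0.31,0.17,0.12,0.12,0.10,0.08,0.18
Valencia,0.17,0.12,0.09,0.13,0.10,0.14,0.06,0.10,0.06,0.08,0.07,0.10
Vitoria,0.14,0.23,0.22,0.21,0.10,0.06,0.05,0.07,0.09,0.08,0.08,0.12
Mean,0.21,0.20,0.17,0.17,0.15,0.14,0.11,0.09,0.09,0.09,0.07,
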