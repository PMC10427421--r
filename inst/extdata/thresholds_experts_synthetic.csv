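expert,melanoma_excise,malignancy_excise,bcc_excise,akiec_local,monitor
e01,0.15,0.50,0.30,0.20,0.10
e02,0.20,0.55,0.35,0.25,0.12
e03,0.10,0.40,0.25,0.15,0.08
e04,0.25,0.60,0.40,0.30,0.15
e05,0.18,0.50,0.30,0.20,0.10
e06,0.12,0.45,0.28,0.18,0.05
e07,0.22,0.50,0.32,0.22,0.12
e08,0.30,0.65,0.45,0.35,0.20
e09,0.16,0.48,0.30,0.20,0.10
e10,0.20,0.52,0.33,0.24,0.11
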