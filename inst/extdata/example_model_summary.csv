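dataset,model,wonEnv,wonEnvPct,wonTrait,wonTraitPct,nrmse,re
ds2_2020,M3,113,50.22,20,44.44,3.02,43.63
ds2_2020,M6,140,62.22,40,88.89,3.07,41.31
ds3_2021,M3,147,46.67,16,35.56,6.89,56.73
ds3_2021,M6,184,58.41,32,71.11,5.99,80.28
ds4_2022,M3,138,57.50,30,66.67,2.43,39.60
ds4_2022,M6,167,69.58,37,82.22,2.12,60.36
ds5_all,M3,435,50.00,26,57.78,5.01,97.67
ds5_all,M6,432,49.66,20,44.44,5.46,81.40
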