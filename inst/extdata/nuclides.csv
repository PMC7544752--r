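name,half_life_s,alpha_energy_MeV,successor
po218,183,6,pb214
pb214,1608,NA,bi214
bi214,1182,7.69,pb210
pb210,Inf,NA,NA
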