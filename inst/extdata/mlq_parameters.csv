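label,role,alpha,beta,delta,lam,alpha_beta
C1,acutely responding breast cancer,0.3,0.03,0.15,0.693,10
C2,slowly responding breast cancer,0.2,0.052,0.15,0.693,3.85
N1,radiosensitive normal tissue,0.366,0.118,0.15,0.693,3.1
N2,moderately radiosensitive normal tissue,0.211,0.068,0.15,0.693,3.1
N3,radioresistant normal tissue,0.108,0.035,0.15,0.693,3.1
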