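parameter,value,unit,note
alpha_beta,3,Gy,xerostomia endpoint
mu,0.46,1/h,sublethal damage repair rate
injected_activity,100,kBq/kg,assumed per-kg injection activity
rbe_exp,5,dimensionless,experimental high-LET RBE
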