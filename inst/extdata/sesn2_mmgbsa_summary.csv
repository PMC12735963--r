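system,component,mean,sd,n
leucine,dG_bind,-37.60,2.39,3
isoleucine,dG_bind,-34.47,1.98,3
valine,dG_bind,-30.32,3.18,3
leucine,dE_vdW,-28.09,1.28,3
isoleucine,dE_vdW,-25.92,1.38,3
valine,dE_vdW,-21.96,1.29,3
leucine,dE_Coulomb,13.13,3.33,3
isoleucine,dE_Coulomb,14.59,2.89,3
valine,dE_Coulomb,11.27,2.15,3
leucine,dG_Lipo,-8.25,0.59,3
isoleucine,dG_Lipo,-7.42,0.45,3
valine,dG_Lipo,-5.92,0.61,3
leucine,dG_SolvGB,-12.30,1.87,3
isoleucine,dG_SolvGB,-13.12,1.55,3
valine,dG_SolvGB,-11.10,1.93,3
leucine,E_StrainLig,0.66,0.62,3
isoleucine,E_StrainLig,0.52,0.27,3
valine,E_StrainLig,0.41,0.32,3
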