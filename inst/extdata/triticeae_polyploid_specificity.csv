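species,ploidy,genome_formula,specific
Ae. crassa,6,Dcr1 Dcr2 Xcr,684
Ae. vavilovii,6,Dva Xva Sva,2153
Ae. ventricosa,4,Dv Nv,3027
Ae. cylindrica,4,CD,4759
Ae. juvenalis,6,Xj Dj Uj,187
Ae. kotschyi,4,Sk Uk,2271
Ae. biuncialis,4,Ub Mb,2601
Ae. triuncialis,4,Ct Ut,2051
Ae. ovata,4,Ug Mg,3163
Ae. triaristata,6,Un Xn Nn,2215
Ae. columnaris,4,Uc Xc,2470
Ae. variabilis,4,Sp Up,2683
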