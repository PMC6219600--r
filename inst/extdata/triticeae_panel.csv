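sample_id,species,ploidy,genome_formula,role
KU-12007,Ae. mutica,2,T,analyzer
KU-2-5,Ae. speltoides,2,S,analyzer
KU-4-1,Ae. longissima,2,Sl,analyzer
KU-5-3,Ae. sharonensis,2,Ssh,analyzer
KU-4-6,Ae. searsii,2,Ss,analyzer
KU-3-1,Ae. bicornis,2,Sb,analyzer
KU-2159,Ae. tauschii,2,D,analyzer
KU-5860,Ae. caudata,2,C,analyzer
KU-17-1,Ae. comosa,2,M,analyzer
KU-19-3,Ae. uniaristata,2,N,analyzer
KU-8-2,Ae. umbellulata,2,U,analyzer
KU-7-1,Ae. cylindrica,4,CD,target
KU-22-1,Ae. ventricosa,4,Dv Nv,target
KU-9-1,Ae. ovata,4,Ug Mg,target
KU-11-1,Ae. columnaris,4,Uc Mc,target
KU-13-6,Ae. kotschyi,4,Sk Uk,target
KU-15-1,Ae. triuncialis,4,Ct Ut,target
KU-13-1,Ae. variabilis,4,Sp Up,target
KU-12-1,Ae. biuncialis,4,Ub Mb,target
KU-10-1,Ae. triaristata,6,Un Mn Nn,target
KU-21-1,Ae. crassa,6,Dc Dc Mc,target
KU-21-7,Ae. vavilovii,6,Dv Mv Sv,target
KU-23-3,Ae. juvenalis,6,Dj Mj Uj,target
KU-199-11,T. urartu,2,Au,analyzer
KT001-001,T. boeoticum,2,Ab,analyzer
KT009-17,T. durum,4,AB,target
KU-491,T. dicoccum,4,AB,target
KU-108-1,T. dicoccoides,4,AB,target
KU-196-1,T. araraticum,4,AG,target
KT020-003,T. aestivum,6,ABD,reference
KU-260,T. aestivum,6,ABD,reference
KT018-002,T. macha,6,ABD,target
TACBOW0071,S. cereale,2,R,analyzer
TACBOW0119,D. villosum,2,V,analyzer
TACBOW0116,H. vulgare,2,H,analyzer
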