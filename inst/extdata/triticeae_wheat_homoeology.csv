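species,subgenome,shared,specific
T. aestivum,A,16901,4688
T. aestivum,B,13415,7227
T. aestivum,D,30187,5167
T. urartu,A,6114,3672
T. urartu,B,1249,95
T. urartu,D,2763,93
T. boeoticum,A,5492,753
T. boeoticum,B,1365,71
T. boeoticum,D,2870,59
Ae. mutica,A,1824,1348
Ae. mutica,B,2331,1966
Ae. mutica,D,4690,2284
Ae. speltoides,A,1139,1129
Ae. speltoides,B,2507,4405
Ae. speltoides,D,3335,1883
Ae. longissima,A,2301,392
Ae. longissima,B,3513,755
Ae. longissima,D,6831,594
Ae. sharonensis,A,2294,336
Ae. sharonensis,B,3487,769
Ae. sharonensis,D,6799,632
Ae. bicornis,A,2018,379
Ae. bicornis,B,3026,756
Ae. bicornis,D,6258,638
Ae. searsii,A,1915,156
Ae. searsii,B,2610,495
Ae. searsii,D,5558,265
Ae. tauschii,A,817,99
Ae. tauschii,B,934,174
Ae. tauschii,D,8988,7568
Ae. caudata,A,1849,1120
Ae. caudata,B,1955,1013
Ae. caudata,D,5321,1848
Ae. comosa,A,1959,1022
Ae. comosa,B,2126,1102
Ae. comosa,D,5545,1904
Ae. uniaristata,A,1805,672
Ae. uniaristata,B,2049,724
Ae. uniaristata,D,5155,1254
Ae. umbellulata,A,2014,928
Ae. umbellulata,B,2055,1017
Ae. umbellulata,D,5174,1653
S. cereale,A,699,23
S. cereale,B,959,64
S. cereale,D,1840,30
D. villosum,A,566,20
D. villosum,B,793,44
D. villosum,D,1538,16
H. vulgare,A,291,8
H. vulgare,B,431,19
H. vulgare,D,824,9
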