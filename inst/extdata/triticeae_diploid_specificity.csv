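species,total,specific
Ae. mutica,12238,837
Ae. speltoides,9330,699
Ae. longissima,18321,761
Ae. sharonensis,18205,723
Ae. bicornis,16465,598
Ae. searsii,15402,1633
Ae. tauschii,20288,7420
Ae. caudata,19086,6514
Ae. comosa,17377,3941
Ae. uniaristata,16719,4003
Ae. umbellulata,19523,6627
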