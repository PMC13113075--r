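phase,condition,n_female,n_male,n_total,n_pitch_missing
farrowing,pain,60,60,120,0
farrowing,hunger,61,60,121,0
farrowing,cold,63,60,123,0
farrowing,normal,59,59,118,0
nursery,pain,62,55,117,11
nursery,hunger,60,56,116,0
nursery,thirst,60,60,120,3
nursery,cold,60,63,123,0
nursery,normal,61,58,119,3
growing,pain,60,66,126,23
growing,hunger,55,57,112,3
growing,thirst,57,60,117,8
growing,heat,57,58,115,16
growing,normal,59,66,125,8
finishing,pain,56,56,112,18
finishing,hunger,49,56,105,66
finishing,thirst,59,55,114,0
finishing,heat,52,56,108,61
finishing,normal,54,56,110,21
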