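stratum_var,level,n_schools,n_desert,n_swamp,n_both
sector,Public,1737,295,1666,224
sector,Private,1422,179,1398,156
income_tercile,Lowest,753,260,675,182
income_tercile,Middle,1135,104,1130,99
income_tercile,Highest,1271,110,1259,99
deprivation,High,538,176,499,138
deprivation,Medium,2025,234,1973,182
deprivation,Low,596,64,592,60
segregation,High,390,133,352,95
segregation,Medium,1412,178,1371,137
segregation,Low,1357,163,1341,148
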