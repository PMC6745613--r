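"area_id","Y","N"
"A001",120,210
"A002",114,220
"A003",110,243
"A004",91,199
"A005",NA,NA
"A006",93,228
"A007",45,101
"A008",101,235
"A009",117,215
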