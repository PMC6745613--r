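country,vaccine,children,vaccinated,printed_pct
Afghanistan,MCV1,5704,3443,60.4
Afghanistan,DTP1,5704,4166,73.0
Afghanistan,DTP2,5704,3875,67.9
Afghanistan,DTP3,5704,3293,57.7
Pakistan,MCV1,2074,1274,61.4
Pakistan,DTP1,2074,1633,78.7
Pakistan,DTP2,2074,1508,72.7
Pakistan,DTP3,2074,1352,65.2
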