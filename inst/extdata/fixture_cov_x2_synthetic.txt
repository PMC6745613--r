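0.1976 1.8011 0.3426 1.3399 0.0947 1.3689 0.2133 1.6707 0.7976 1.7781 0.8637 0.9509
0.1226 0.3488 1.7882 0.6704 0.6348 0.2193 0.3631 1.2385 1.85 0.2433 1.0332 0.2443
0.9127 1.6005 2.2158 0.1838 0.8041 2.08 1.6342 0.1444 0.8615 0.6663 0.345 2.2022
2.5145 0.8153 0.7494 0.2932 0.5018 0.738 1.3325 1.017 0.2035 1.4205 1.1364 0.2838
0.4251 0.6615 2.5038 0.4567 0.5928 0.9778 0.1937 1.0927 2.104 2.0921 0.1428 1.6016
0.8497 0.6761 0.3335 1.2459 0.9954 0.8074 0.7512 0.3154 1.8458 2.2467 0.8513 1.1243
0.8235 1.6174 0.8845 0.7363 0.8634 0.8585 1.8182 0.8296 0.2093 0.462 1.2558 2.7075
0.6725 0.3312 0.3767 1.2059 0.2097 0.138 0.5913 0.3915 0.7574 0.5465 0.1587 0.9519
2.032 0.3097 0.7439 0.9122 2.2948 3.5652 0.2911 0.1349 0.6177 1.004 4.0752 0.541
0.9315 0.4918 1.2186 0.2341 2.3495 1.5501 0.1962 0.7972 0.3302 0.5419 0.5543 1.3477
0.4302 0.9576 1.4684 1.0002 1.0909 0.1749 0.2341 1.4793 1.7296 2.3808 0.9816 1.1775
2.2325 1.905 1.3936 0.8322 2.52 0.5155 0.5173 1.8891 0.3004 1.5344 0.458 1.1292
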