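0.0205 -0.4581 -0.3143 -0.2695 -0.1143 -1.4698 -2.5555 -0.3739 0.1403 -0.6205 -0.8422 -0.3931
-1.0462 -0.4776 -1.1863 0.0621 -0.3681 0.7577 0.1051 1.2749 -0.3359 1.0914 -1.2897 -0.2224
-1.455 0.3959 -0.6923 0.7033 -0.5015 -0.7452 -0.9081 1.1779 0.4673 0.9548 -0.0964 0.2873
0.606 1.1427 -0.7408 0.9184 0.1691 -1.538 -0.5995 2.1077 -1.3047 -1.34 -0.6459 -0.1649
0.1562 0.2885 -1.1407 -0.013 -0.5219 -1.613 -0.9344 2.1036 -1.0995 -0.5605 0.9904 -0.7584
0.254 -0.2752 -3.0533 0.0918 1.0506 -1.2204 1.0453 -2.3098 2.1494 0.3592 0.5098 0.6361
-0.4324 -1.179 0.7613 -0.194 -0.5077 1.4231 -0.088 0.1643 -1.055 -0.5949 0.4159 -1.0246
-0.6717 -0.2866 -0.9082 0.2214 0.2378 0.5659 0.3864 0.8888 -1.7029 -0.7698 0.0986 -1.6573
0.5892 -0.2056 0.279 0.9704 1.1494 0.0739 -0.3839 -0.361 0.165 -0.3495 0.7105 -0.6814
-0.2277 -0.5326 -1.0717 -2.2744 -0.6882 1.0204 0.747 -0.4849 -0.7 -0.3253 1.2635 -3.0708
-0.6576 1.5548 -0.2152 -1.6885 1.819 0.1752 0.4013 1.8863 -0.1017 -1.4087 1.4912 -1.7956
1.7378 -1.65 1.0028 -0.7136 -0.5674 -1.2861 -0.4553 0.7338 1.4065 -0.3731 1.8987 -0.3509
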