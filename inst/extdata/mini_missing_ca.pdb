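ATOM      1  CA  ALA A   1      11.639   6.071  -5.147  1.00 90.00           C
ATOM      2  N   GLY A   2      12.000   3.000  -4.500  1.00 85.50           N
ATOM      3  C   GLY A   2      12.600   2.100  -3.700  1.00 85.50           C
ATOM      4  CA  LEU A   3      13.500   0.500  -1.000  1.00 70.00           C
END
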