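ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 90.00           N
ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00 90.00           C
ATOM      3  CA  GLY A   2      12.345   2.500  -4.000  1.00 85.50           C
ATOM      4  N   LEU A   3      13.000   1.000  -2.000  1.00 70.00           N
ATOM      5  CA  LEU A   3      13.500   0.500  -1.000  1.00 70.00           C
END
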