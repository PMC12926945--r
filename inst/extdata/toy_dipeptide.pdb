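ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C
ATOM      6  N   SER A   2       3.332   1.536   0.000  1.00  0.00           N
ATOM      7  CA  SER A   2       3.988   2.840   0.000  1.00  0.00           C
ATOM      8  C   SER A   2       5.504   2.693   0.000  1.00  0.00           C
ATOM      9  O   SER A   2       6.030   1.581   0.000  1.00  0.00           O
ATOM     10  CB  SER A   2       3.563   3.659   1.221  1.00  0.00           C
ATOM     11  OG  SER A   2       2.155   3.844   1.221  1.00  0.00           O
HETATM   12  O   HOH W   3       4.500   5.500   1.500  1.00  0.00           O
HETATM   13  O   HOH W   4       9.000   9.000   9.000  1.00  0.00           O
END
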