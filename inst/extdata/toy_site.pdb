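REMARK   2 RESOLUTION.     1.80 ANGSTROMS.
ATOM      1  N   SER A   1       0.419   6.185  -1.800  1.00 15.20           N
ATOM      2  CA  SER A   1       1.119   5.385  -1.800  1.00 14.10           C
ATOM      3  C   SER A   1       2.219   5.985  -1.400  1.00 14.80           C
ATOM      4  O   SER A   1       2.419   7.085  -1.200  1.00 16.00           O
ATOM      5  N   SER A   2      -5.745   2.991  -0.600  1.00 16.20           N
ATOM      6  CA  SER A   2      -5.045   2.191  -0.600  1.00 15.10           C
ATOM      7  C   SER A   2      -3.945   2.791  -0.200  1.00 15.80           C
ATOM      8  O   SER A   2      -3.745   3.891  -0.000  1.00 17.00           O
ATOM      9  N   SER A   3      -3.872  -3.693   0.600  1.00 17.20           N
ATOM     10  CA  SER A   3      -3.172  -4.493   0.600  1.00 16.10           C
ATOM     11  C   SER A   3      -2.072  -3.893   1.000  1.00 16.80           C
ATOM     12  O   SER A   3      -1.872  -2.793   1.200  1.00 18.00           O
ATOM     13  N   SER A   4       3.054  -3.220   1.800  1.00 18.20           N
ATOM     14  CA  SER A   4       3.754  -4.020   1.800  1.00 17.10           C
ATOM     15  C   SER A   4       4.854  -3.420   2.200  1.00 17.80           C
ATOM     16  O   SER A   4       5.054  -2.320   2.400  1.00 19.00           O
HETATM   17  C1  LIG A 900       0.000   0.000   0.000  1.00 18.50           C
HETATM   18  O   HOH A1001       1.902   2.385  -1.100  1.00 23.74           O
HETATM   19  O   HOH A1002      -0.801   3.510  -0.700  1.00 21.30           O
HETATM   20  O   HOH A1003      -3.739   1.801  -0.300  1.00 35.80           O
HETATM   21  O   HOH A1004      -4.235  -2.039   0.100  1.00 44.10           O
HETATM   22  O   HOH A1005      -1.168  -5.118   0.500  1.00 19.90           O
HETATM   23  O   HOH A1006       3.616  -4.535   0.900  1.00 28.40           O
HETATM   24  O   HOH A1007       6.350  -0.000   1.300  1.00 51.20           O
HETATM   25  O   HOH A1101      -6.563  11.222   2.500  1.00 40.00           O
HETATM   26  O   HOH A1102      -6.373 -11.330   5.000  1.00 42.00           O
HETATM   27  O   HOH A1103      12.998   0.219   7.500  1.00 44.00           O
END
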