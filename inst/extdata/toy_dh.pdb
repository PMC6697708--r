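REMARK 465 MISSING RESIDUES
REMARK 465   M RES C SSSEQI
REMARK 465     PRO A    14 
REMARK 465     ALA A    15 
REMARK 465     ALA A    16 
REMARK 465     ALA A    17 
ATOM      1  CA  LEU A   1       0.000   0.000   0.000  1.00 22.40           C
ATOM      2  CA  PRO A   2      -1.838   0.723  -3.246  1.00 17.94           C
ATOM      3  CA  PHE A   3      -2.328   2.172  -6.725  1.00 21.88           C
ATOM      4  CA  ALA A   4      -3.786   2.635 -10.204  1.00 18.91           C
ATOM      5  CA  HIS A   5      -5.758   2.828 -13.446  1.00 21.03           C
ATOM      6  CA  ALA A   6      -8.568   2.574 -15.991  1.00 19.29           C
ATOM      7  CA  ALA A   7     -11.239   1.727 -18.558  1.00 22.65           C
ATOM      8  CA  ALA A   8     -13.982  -0.330 -20.196  1.00 17.72           C
ATOM      9  CA  GLY A   9     -15.937  -2.118 -22.920  1.00 22.83           C
ATOM     10  CA  ALA A  10     -18.012  -3.600 -25.738  1.00 18.80           C
ATOM     11  CA  ALA A  11     -20.659  -5.611 -27.579  1.00 19.12           C
ATOM     12  CA  ALA A  12     -23.650  -7.680 -28.680  1.00 20.49           C
ATOM     13  CA  ALA A  13     -26.959  -8.375 -30.414  1.00 21.19           C
ATOM     14  CA  ALA A  18     -36.331 -23.197 -29.788  1.00 17.99           C
ATOM     15  CA  ALA A  19     -37.337 -26.438 -28.077  1.00 22.54           C
ATOM     16  CA  ASP A  20     -38.186 -29.067 -25.469  1.00 22.25           C
ATOM     17  CA  ALA A  21     -39.851 -30.531 -22.382  1.00 21.68           C
ATOM     18  CA  LEU A  22     -41.945 -31.397 -19.332  1.00 64.93           C
ATOM     19  CA  ALA A  23     -44.535 -33.158 -17.180  1.00 58.72           C
ATOM     20  CA  LEU A  24     -46.484 -34.635 -14.271  1.00 62.42           C
ATOM     21  CA  ALA A  25     -48.546 -35.538 -11.210  1.00 61.42           C
ATOM     22  CA  ARG A  26     -49.959 -37.248  -8.125  1.00 59.59           C
ATOM     23  CA  ALA A  27     -52.469 -38.289  -5.468  1.00 19.16           C
ATOM     24  CA  ALA A  28     -54.994 -40.530  -3.724  1.00 20.61           C
ATOM     25  CA  ALA A  29     -56.547 -43.761  -2.464  1.00 19.94           C
ATOM     26  CA  ALA A  30     -57.589 -47.415  -2.472  1.00 20.21           C
ATOM     27  ND1 HIS A   5      -6.155   5.354 -12.664  1.00 21.03           N
ATOM     28  NE2 HIS A   5      -4.346   4.118 -12.860  1.00 21.03           N
ATOM     29  OD1 ASP A  20      -2.044   2.545 -13.110  1.00 22.25           O
ATOM     30  OD2 ASP A  20      -1.221   1.983 -13.199  1.00 22.25           O
TER
HETATM   31  P   PNS A 900       0.356 -17.527 -18.055  1.00 30.00           P
HETATM   32  C3  PNS A 900     -11.554 -14.244 -28.841  1.00 30.00           C
END
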