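REMARK   SYNTHETIC stand-in structure generated by pathflow
REMARK   two cholesterol molecules at a fixed centroid separation
ATOM      1  CA  ALA A   1      10.300   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ALA A   2       7.601   2.265   1.500  1.00  0.00           C
ATOM      3  CA  ALA A   3       5.839  -0.787   3.000  1.00  0.00           C
ATOM      4  CA  ALA A   4       9.150  -1.992   4.500  1.00  0.00           C
ATOM      5  CA  ALA A   5       9.762   1.478   6.000  1.00  0.00           C
ATOM      6  CA  ALA A   6       6.238   1.478   7.500  1.00  0.00           C
ATOM      7  CA  ALA A   7       6.850  -1.992   9.000  1.00  0.00           C
ATOM      8  CA  ALA A   8      10.161  -0.787  10.500  1.00  0.00           C
ATOM      9  CA  ALA A   9       8.399   2.265  12.000  1.00  0.00           C
ATOM     10  CA  ALA A  10       5.700   0.000  13.500  1.00  0.00           C
ATOM     11  CA  ALA A  11       8.399  -2.265  15.000  1.00  0.00           C
ATOM     12  CA  ALA A  12      10.161   0.787  16.500  1.00  0.00           C
ATOM     13  CA  ALA A  13       6.850   1.992  18.000  1.00  0.00           C
ATOM     14  CA  ALA A  14       6.238  -1.478  19.500  1.00  0.00           C
ATOM     15  CA  ALA A  15       9.762  -1.478  21.000  1.00  0.00           C
ATOM     16  CA  ALA A  16       9.150   1.992  22.500  1.00  0.00           C
ATOM     17  CA  ALA A  17       5.839   0.787  24.000  1.00  0.00           C
ATOM     18  CA  ALA A  18       7.601  -2.265  25.500  1.00  0.00           C
ATOM     19  CA  ALA A  19      10.300  -0.000  27.000  1.00  0.00           C
ATOM     20  CA  ALA A  20       7.601   2.265  28.500  1.00  0.00           C
ATOM     21  CA  ALA A  21       5.839  -0.787  30.000  1.00  0.00           C
ATOM     22  CA  ALA A  22       9.150  -1.992  31.500  1.00  0.00           C
ATOM     23  CA  ALA A  23       9.762   1.478  33.000  1.00  0.00           C
ATOM     24  CA  ALA A  24       6.238   1.478  34.500  1.00  0.00           C
ATOM     25  CA  ALA A  25       6.850  -1.992  36.000  1.00  0.00           C
ATOM     26  CA  ALA A  26      10.161  -0.787  37.500  1.00  0.00           C
ATOM     27  CA  ALA A  27       8.399   2.265  39.000  1.00  0.00           C
ATOM     28  CA  ALA A  28       5.700  -0.000  40.500  1.00  0.00           C
ATOM     29  CA  ALA A  29       8.399  -2.265  42.000  1.00  0.00           C
ATOM     30  CA  ALA A  30      10.161   0.787  43.500  1.00  0.00           C
ATOM     31  CA  ALA A  31       6.850   1.992  45.000  1.00  0.00           C
ATOM     32  CA  ALA A  32       6.238  -1.478  46.500  1.00  0.00           C
ATOM     33  CA  ALA A  33       9.762  -1.478  48.000  1.00  0.00           C
ATOM     34  CA  ALA A  34       9.150   1.992  49.500  1.00  0.00           C
ATOM     35  CA  ALA A  35       5.839   0.787  51.000  1.00  0.00           C
ATOM     36  CA  ALA A  36       7.601  -2.265  52.500  1.00  0.00           C
ATOM     37  CA  ALA A  37      10.300  -0.000  54.000  1.00  0.00           C
ATOM     38  CA  ALA A  38       7.601   2.265  55.500  1.00  0.00           C
ATOM     39  CA  ALA A  39       5.839  -0.787  57.000  1.00  0.00           C
ATOM     40  CA  ALA A  40       9.150  -1.992  58.500  1.00  0.00           C
HETATM   41  C1  CLR L1201       3.263  -0.141  57.243  1.00  0.00           C
HETATM   42  C2  CLR L1201       3.290  -0.875  55.898  1.00  0.00           C
HETATM   43  C3  CLR L1201       4.692  -0.728  55.248  1.00  0.00           C
HETATM   44  C4  CLR L1201       5.071   0.699  54.830  1.00  0.00           C
HETATM   45  C5  CLR L1201       6.505   0.796  54.290  1.00  0.00           C
HETATM   46  C6  CLR L1201       7.541   1.310  55.309  1.00  0.00           C
HETATM   47  C7  CLR L1201       8.903   1.465  54.627  1.00  0.00           C
HETATM   48  C8  CLR L1201       7.679   0.410  56.535  1.00  0.00           C
HETATM   49  C9  CLR L1201       2.134  -0.446  54.954  1.00  0.00           C
HETATM   50  C10 CLR L1201       2.175  -1.207  53.597  1.00  0.00           C
HETATM   51  C11 CLR L1201       0.729  -1.323  53.099  1.00  0.00           C
HETATM   52  C12 CLR L1201      -0.061  -0.448  54.060  1.00  0.00           C
HETATM   53  C13 CLR L1201      -1.580  -0.643  54.131  1.00  0.00           C
HETATM   54  C14 CLR L1201      -2.227  -0.494  52.744  1.00  0.00           C
HETATM   55  C15 CLR L1201      -3.666  -0.077  52.761  1.00  0.00           C
HETATM   56  C16 CLR L1201      -4.363   0.255  53.865  1.00  0.00           C
HETATM   57  C17 CLR L1201      -5.738   0.874  53.706  1.00  0.00           C
HETATM   58  C18 CLR L1201      -6.622   0.876  54.957  1.00  0.00           C
HETATM   59  O1  CLR L1201      -7.229  -0.403  55.154  1.00  0.00           O
HETATM   60  C19 CLR L1201      -5.889   1.285  56.237  1.00  0.00           C
HETATM   61  C20 CLR L1201      -4.360   1.332  56.112  1.00  0.00           C
HETATM   62  C21 CLR L1201      -3.750   0.185  55.267  1.00  0.00           C
HETATM   63  C22 CLR L1201      -4.094  -1.178  55.916  1.00  0.00           C
HETATM   64  C23 CLR L1201      -2.186   0.371  55.147  1.00  0.00           C
HETATM   65  C24 CLR L1201      -1.432   0.355  56.501  1.00  0.00           C
HETATM   66  C25 CLR L1201       0.099   0.438  56.363  1.00  0.00           C
HETATM   67  C26 CLR L1201       0.657  -0.642  55.419  1.00  0.00           C
HETATM   68  C27 CLR L1201       0.452  -2.046  56.038  1.00  0.00           C
HETATM   69  C1  CLR L1202       3.263  -0.141  12.243  1.00  0.00           C
HETATM   70  C2  CLR L1202       3.290  -0.875  10.898  1.00  0.00           C
HETATM   71  C3  CLR L1202       4.692  -0.728  10.248  1.00  0.00           C
HETATM   72  C4  CLR L1202       5.071   0.699   9.830  1.00  0.00           C
HETATM   73  C5  CLR L1202       6.505   0.796   9.290  1.00  0.00           C
HETATM   74  C6  CLR L1202       7.541   1.310  10.309  1.00  0.00           C
HETATM   75  C7  CLR L1202       8.903   1.465   9.627  1.00  0.00           C
HETATM   76  C8  CLR L1202       7.679   0.410  11.535  1.00  0.00           C
HETATM   77  C9  CLR L1202       2.134  -0.446   9.954  1.00  0.00           C
HETATM   78  C10 CLR L1202       2.175  -1.207   8.597  1.00  0.00           C
HETATM   79  C11 CLR L1202       0.729  -1.323   8.099  1.00  0.00           C
HETATM   80  C12 CLR L1202      -0.061  -0.448   9.060  1.00  0.00           C
HETATM   81  C13 CLR L1202      -1.580  -0.643   9.131  1.00  0.00           C
HETATM   82  C14 CLR L1202      -2.227  -0.494   7.744  1.00  0.00           C
HETATM   83  C15 CLR L1202      -3.666  -0.077   7.761  1.00  0.00           C
HETATM   84  C16 CLR L1202      -4.363   0.255   8.865  1.00  0.00           C
HETATM   85  C17 CLR L1202      -5.738   0.874   8.706  1.00  0.00           C
HETATM   86  C18 CLR L1202      -6.622   0.876   9.957  1.00  0.00           C
HETATM   87  O1  CLR L1202      -7.229  -0.403  10.154  1.00  0.00           O
HETATM   88  C19 CLR L1202      -5.889   1.285  11.237  1.00  0.00           C
HETATM   89  C20 CLR L1202      -4.360   1.332  11.112  1.00  0.00           C
HETATM   90  C21 CLR L1202      -3.750   0.185  10.267  1.00  0.00           C
HETATM   91  C22 CLR L1202      -4.094  -1.178  10.916  1.00  0.00           C
HETATM   92  C23 CLR L1202      -2.186   0.371  10.147  1.00  0.00           C
HETATM   93  C24 CLR L1202      -1.432   0.355  11.501  1.00  0.00           C
HETATM   94  C25 CLR L1202       0.099   0.438  11.363  1.00  0.00           C
HETATM   95  C26 CLR L1202       0.657  -0.642  10.419  1.00  0.00           C
HETATM   96  C27 CLR L1202       0.452  -2.046  11.038  1.00  0.00           C
END
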