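ATOM      1  CA  ALA A   1     -28.456 -82.104  18.806  1.00  0.00           C  
ATOM      2  CA  ALA A   2     -40.912 -69.851 -19.620  1.00  0.00           C  
ATOM      3  CA  ALA A   3     -20.864 -76.453  -1.658  1.00  0.00           C  
ATOM      4  CA  ALA A   4     -31.235 -51.387  -6.037  1.00  0.00           C  
ATOM      5  CA  ALA A   5      -1.002 -69.843 -51.886  1.00  0.00           C  
ATOM      6  CA  ALA A   6     -25.898 -68.701 -23.736  1.00  0.00           C  
ATOM      7  CA  ALA A   7     -42.574 -55.105  -2.768  1.00  0.00           C  
ATOM      8  CA  ALA A   8     -41.784 -50.459  21.493  1.00  0.00           C  
ATOM      9  CA  ALA A   9      -3.463 -84.470 -13.771  1.00  0.00           C  
ATOM     10  CA  ALA A  10     -26.790 -77.164 -18.064  1.00  0.00           C  
ATOM     11  CA  ALA A  11     -26.629 -68.828  -0.032  1.00  0.00           C  
ATOM     12  CA  ALA A  12     -16.561 -62.354   6.174  1.00  0.00           C  
ATOM     13  CA  ALA A  13     -36.027 -74.651  11.967  1.00  0.00           C  
ATOM     14  CA  ALA A  14     -27.871 -49.833 -20.268  1.00  0.00           C  
ATOM     15  CA  ALA A  15     -24.973 -92.965  38.830  1.00  0.00           C  
ATOM     16  CA  ALA A  16     -40.192 -85.099  36.933  1.00  0.00           C  
ATOM     17  CA  ALA A  17      -3.251 -97.459 -27.266  1.00  0.00           C  
ATOM     18  CA  ALA A  18     -20.871 -91.815  19.155  1.00  0.00           C  
ATOM     19  CA  ALA A  19     -19.019 -96.235  39.727  1.00  0.00           C  
ATOM     20  CA  ALA A  20     -12.971 -98.064   9.273  1.00  0.00           C  
ATOM     21  CA  ALA A  21     -37.983 -69.814   1.385  1.00  0.00           C  
ATOM     22  CA  ALA A  22     -58.344 -73.682  26.187  1.00  0.00           C  
ATOM     23  CA  ALA A  23     -13.807 -73.536  36.150  1.00  0.00           C  
ATOM     24  CA  ALA A  24      -6.022 -78.135   9.714  1.00  0.00           C  
ATOM     25  CA  ALA A  25     -20.436-102.236  30.035  1.00  0.00           C  
ATOM     26  CA  ALA A  26      16.300 -78.745 -31.900  1.00  0.00           C  
ATOM     27  CA  ALA A  27     -47.798 -55.726  11.746  1.00  0.00           C  
ATOM     28  CA  ALA A  28     -36.976 -65.814   0.956  1.00  0.00           C  
ATOM     29  CA  ALA A  29     -28.552 -69.594 -47.758  1.00  0.00           C  
ATOM     30  CA  ALA A  30      11.680 -85.336 -37.618  1.00  0.00           C  
ATOM     31  CA  ALA A  31     -44.503 -66.513 -19.945  1.00  0.00           C  
ATOM     32  CA  ALA A  32     -54.767 -63.327  10.327  1.00  0.00           C  
ATOM     33  CA  ALA A  33     -49.593 -53.046   7.541  1.00  0.00           C  
ATOM     34  CA  ALA A  34     -55.133 -53.707  14.342  1.00  0.00           C  
ATOM     35  CA  ALA A  35     -11.423 -82.930 -37.843  1.00  0.00           C  
ATOM     36  CA  ALA A  36     -63.403 -63.962  24.775  1.00  0.00           C  
ATOM     37  CA  ALA A  37      -0.082 -84.875 -19.247  1.00  0.00           C  
ATOM     38  CA  ALA A  38      13.130 -74.310 -29.393  1.00  0.00           C  
ATOM     39  CA  ALA A  39     -13.440 -95.112  21.852  1.00  0.00           C  
ATOM     40  CA  ALA A  40     -17.868 -81.596 -23.694  1.00  0.00           C  
ATOM     41  CA  ALA A  41     -18.621 -95.060  26.133  1.00  0.00           C  
ATOM     42  CA  ALA A  42     -18.187 -70.422 -16.074  1.00  0.00           C  
ATOM     43  CA  ALA A  43     -52.688 -68.958   0.124  1.00  0.00           C  
ATOM     44  CA  ALA A  44     -28.881 -64.311  21.298  1.00  0.00           C  
ATOM     45  CA  ALA A  45       8.126-103.979 -27.308  1.00  0.00           C  
ATOM     46  CA  ALA A  46      -1.165 -72.130 -48.902  1.00  0.00           C  
ATOM     47  CA  ALA A  47     -16.193 -60.799 -43.738  1.00  0.00           C  
ATOM     48  CA  ALA A  48     -37.087 -60.043   7.145  1.00  0.00           C  
ATOM     49  CA  ALA A  49     -32.004 -70.775  37.466  1.00  0.00           C  
ATOM     50  CA  ALA A  50     -21.785 -89.146  -0.440  1.00  0.00           C  
ATOM     51  CA  TYR A 701      -7.876 -64.056  32.854  1.00  0.00           C  
ATOM     52  CA  TYR A 702      -6.808 -65.369  32.043  1.00  0.00           C  
ATOM     53  CA  TYR A 703      -5.979 -63.970  31.334  1.00  0.00           C  
ATOM     54  CA  TYR A 704      -5.693 -65.035  33.526  1.00  0.00           C  
ATOM     55  CA  TYR A 801     -29.099 -44.622  24.288  1.00  0.00           C  
ATOM     56  CA  TYR A 802     -26.710 -45.447  26.097  1.00  0.00           C  
ATOM     57  CA  TYR A 803     -27.692 -44.931  24.885  1.00  0.00           C  
ATOM     58  CA  TYR A 804     -28.292 -45.031  23.097  1.00  0.00           C  
ATOM     59  CA  GLU A1201      -3.780 -45.058 -30.807  1.00  0.00           C  
ATOM     60  CA  GLU A1202      -3.789 -45.442 -33.048  1.00  0.00           C  
ATOM     61  CA  GLU A1203      -2.899 -45.502 -30.662  1.00  0.00           C  
ATOM     62  CA  GLU A1204      -3.256 -44.041 -30.541  1.00  0.00           C  
ATOM     63  CA  ASP A1401      18.091 -65.672 -21.456  1.00  0.00           C  
ATOM     64  CA  ASP A1402      17.420 -64.351 -22.975  1.00  0.00           C  
ATOM     65  CA  ASP A1403      17.290 -65.356 -22.134  1.00  0.00           C  
ATOM     66  CA  ASP A1404      16.662 -63.063 -21.975  1.00  0.00           C  
END   
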