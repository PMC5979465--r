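H SYNI0001
D Synthetic per-residue index for parser tests
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
    1.37  -0.56   0.36   0.63   0.40  -0.11   1.51  -0.09   2.02  -0.06
    1.30   2.29  -1.39  -0.28  -0.13   0.64  -0.28  -2.66  -2.44   1.32
//
H SYNI0002
D Synthetic incomplete index (one missing value)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   -0.31  -1.78  -0.17   1.21   1.90  -0.43  -0.26  -1.76   0.46     NA
   -0.64   0.46   0.70   1.04  -0.61   0.50  -1.72  -0.78  -0.85  -2.41
//
H SYNM0001
D Synthetic symmetric substitution matrix, lower triangle
M rows = ARNDCQEGHILKMFPSTWYV, cols = ARNDCQEGHILKMFPSTWYV
   0.0
   0.2  -0.4
  -0.8   0.8   0.3
   0.8   0.9   0.6  -1.0
  -0.3  -0.1  -0.8   1.0  -1.0
  -0.8  -0.4  -1.0  -0.6  -0.0  -0.4
   0.9   0.6  -0.3   0.2  -0.4   0.9   1.4
  -0.4   0.2  -0.4   0.0  -0.1  -0.4  -1.1   0.7
   0.8  -0.5   0.0   0.5   0.1  -0.9  -0.3  -0.0  -1.1
  -0.9   0.7   0.2  -0.1  -1.1   0.6  -0.0  -0.2  -0.4  -0.7
  -0.1   0.0   0.9   0.7   0.7  -1.2   1.4  -0.3  -0.1   1.0  -1.0
  -0.1  -0.0   1.2   0.2  -0.6  -0.0   0.5   0.5  -0.7  -1.5  -0.5   0.6
   0.2   0.4  -1.1  -0.2   0.0  -0.8   0.6   1.1   0.6  -0.6   0.1  -0.3   0.4
   0.0   0.3   0.8  -0.2   0.3   0.5  -0.9   0.4   0.6  -1.2  -0.6   0.0  -0.8  -1.0
   0.8  -0.8   0.8  -0.2   0.6   0.8   0.4  -0.1  -0.0  -0.7   0.0   0.6   0.9  -0.7   0.2
  -0.2  -0.2  -0.2  -1.0   0.1   0.0   0.6   0.1  -0.6  -0.1   1.4   0.1  -0.4   0.6   0.0  -0.5
  -0.7  -0.1  -1.0  -0.4  -0.7  -0.7  -0.2   1.5  -0.7  -0.4  -0.3   1.5  -0.2   0.4  -0.9   1.3  -0.7
   1.2   1.6  -1.1   0.0   0.6  -0.1  -0.8   0.1   0.2   1.4   0.0   0.4  -0.2  -0.2  -0.9  -0.3   0.4   0.4
   0.5   0.9  -1.2   1.4   0.6  -0.7  -0.2   0.3   1.1   0.8  -0.9  -0.9   0.3  -0.8  -1.0   0.0  -0.9  -1.0   0.2
  -0.8  -0.0  -0.7  -0.6  -0.6   0.2   0.3   0.6   0.1   0.2  -0.6   1.7  -0.2  -0.8  -1.1  -0.1   0.5  -1.2  -0.4  -1.2
//
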