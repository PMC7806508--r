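IGF2BP1
MAGEA1
MAGEA2
MAGEA2B
MAGEA3
MAGEA4
MAGEA6
MAGEA12
MAGEC1
MAGEC2
DUX4
XAGE1B
XAGE1E
CT47A2
CT47A6
CTAG1B
CTAG2
PRAME
SSX2
GAGE1
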