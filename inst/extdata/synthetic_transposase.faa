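>synthetic_transposase synthetic fixture; DDE domain residues 101-230; catalytic D110 D160 E220
MMPNPFCAMEGFCVWFRSHLRAEWAYHYIWAFCYIEEMMRIPGITGEVNPIGSSRNAKYS
VDWAGYFQWHGTQKMTKPSHMMCHPNKNQYMKIGCVHFINRVNINIWMIDKRAHNNMSKL
TNYHMREMGWLQTLQGTNAVFCLIHCYSNLIHIEHYAISDPRHEYTCELEMSSVFKPDAD
IPEFKCWNMMKAYHLYDVQFNDYHQIAFFVFHGFPDELFEEVCSQIDYIKFGMAEHIQAL
KEHDIKMWRYLVNQYKTSEFLVKKSPLMISWEGPKNCMRMQSTMFARGFAPPPDNEFGNV
NPYRFSEAKNAVAQCFIRYDGRWMVWFEDK
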