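# Mean plasma concentrations (mol/L) corresponding to a 100% factor level.
# fII (prothrombin) and fX are the values printed with the model description
# (1.4 uM and ~170 nM); the remaining six follow the literature convention of
# the Hockin/Mann model family. All entries can be overridden at run time.
fII:  1.4e-6
fV:   2.0e-8
fVII: 1.0e-8
fVIII: 7.0e-10
fIX:  9.0e-8
fX:   1.7e-7
TFPI: 2.5e-9
AT:   3.4e-6
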