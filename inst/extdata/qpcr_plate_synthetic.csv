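gene,sample,ct,reference
GAPDH,tumor,24.10,TRUE
GAPDH,tumor,24.12,TRUE
GAPDH,tumor,24.08,TRUE
GAPDH,normal,24.30,TRUE
GAPDH,normal,24.31,TRUE
GAPDH,normal,24.29,TRUE
PTEN,tumor,26.42,FALSE
PTEN,tumor,26.44,FALSE
PTEN,tumor,26.40,FALSE
PTEN,normal,25.30,FALSE
PTEN,normal,25.28,FALSE
PTEN,normal,25.32,FALSE
RGR,tumor,25.92,FALSE
RGR,tumor,25.90,FALSE
RGR,tumor,25.94,FALSE
RGR,normal,25.60,FALSE
RGR,normal,25.62,FALSE
RGR,normal,25.58,FALSE
HHEX,tumor,25.73,FALSE
HHEX,tumor,25.75,FALSE
HHEX,tumor,25.71,FALSE
HHEX,normal,25.41,FALSE
HHEX,normal,25.43,FALSE
HHEX,normal,25.39,FALSE
BICC1,tumor,25.10,FALSE
BICC1,tumor,25.12,FALSE
BICC1,tumor,25.08,FALSE
BICC1,normal,25.30,FALSE
BICC1,normal,25.32,FALSE
BICC1,normal,25.28,FALSE
TRUB1,tumor,24.85,FALSE
TRUB1,tumor,24.87,FALSE
TRUB1,tumor,24.83,FALSE
TRUB1,normal,25.05,FALSE
TRUB1,normal,25.07,FALSE
TRUB1,normal,25.03,FALSE
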