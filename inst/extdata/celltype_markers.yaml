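# Canonical lineage markers for naming aortic cell clusters. Symbols are
# human; pass the mouse orthologs (capitalized-first-letter symbols) for
# mouse data.
SMC: [MYH11, ACTA2, TAGLN, CNN1, MYL9]
EC: [PECAM1, CDH5, VWF, CLDN5]
FB: [DCN, LUM, PDGFRA, COL1A1, FBLN1]
MoMph: [CD68, LYZ, CD14, C1QA, AIF1]
T: [CD3D, CD3E, IL7R, TRAC]
B: [CD79A, CD79B, MS4A1]
NK: [NKG7, GNLY, KLRD1, KLRB1]
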