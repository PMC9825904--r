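complement:
- CFH
- CFI
- CFB
- CFD
- CFP
- C2
- C3
- C4A
- C4B
- C5
- C6
- C7
- C8A
- C8B
- C8G
- C9
- CFHR1
- CFHR2
- CFHR3
- CFHR4
- CFHR5
- CD46
- CD55
- CD59
- CR1
- CR2
- C1QA
- C1QB
- C1QC
- C1R
- C1S
- MASP1
- MASP2
- FCN1
- FCN2
- FCN3
- CSMD1
- CSMD2
- CSMD3
- VTN
- CLU
- SERPING1
- ELANE
lipid:
- LDLR
- APOB
- APOE
- ABCA1
- ABCA7
- CETP
- LIPC
- LPL
- MTTP
- CYP4V2
- ACAT1
- SCARB1
- PLTP
- APOA1
- APOC1
mouse_model:
- LDLR
- APOB
- APOE
- C3
- CFH
- CX3CR1
- CD36
- CCL2
- CCR2
- NFE2L2
- SOD1
- SOD2
- TTR
- VLDLR
- EFEMP1
- MMP2
amd_loci:
- ARMS2
- HTRA1
- SLC16A8
- COL8A1
- COL10A1
- ADAMTS9
- TGFBR1
- VEGFA
- TNFRSF10A
- RAD51B
- B3GLCT
- ARHGAP21
- PILRA
- PILRB
- TSPAN10
- SYN3
- TIMP3
- CTRB1
- CTRB2
- KMT2E
- RORB
- SPEF2
- PRLR
- MMP9
- CFHR5
- CNN2
- APOE
- CETP
- LIPC
- C2
- C3
- C9
- CFI
- CFB
- ABCA7
ird:
  BEST1: AD
  PRPH2: AD
  TIMP3: AD
  EFEMP1: AD
  ELOVL4: AD
  C1QTNF5: AD
  CTNNA1: AD
  FSCN2: AD
  PRDM13: AD
  RP1L1: AD
  PROM1: AD
  HMCN1: AD
  ABCA4: AR
  ABCC6: AR
  CDH3: AR
  MFSD8: AR
  IMPG1: AR
  MERTK: AR
known_ird_events:
- gene: ABCA4
  description: c.5196+1137G>A
- gene: ABCA4
  description: c.4539+2001G>A
- gene: PRPH2
  description: c.-359_+1646del
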