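# Band-math vegetation index definitions.
#
# Each entry gives an arithmetic expression over named bands; a band is
# a wavelength window [lo, hi] in nm summarized by its mean reflectance.
# The named literature indices (mcari, mtci, sipi2, tcari, ari, cri,
# npci, pri2, psri, wi) ship as empty placeholders: their formulas are
# defined in their original references and should be filled in from
# them before use.  Entries with an empty expr are skipped by
# read_index_defs().
indices:
  nd_rededge:
    expr: (A - B)/(A + B)
    bands:
      A: [750, 800]
      B: [680, 700]
  mcari1: {expr: '', bands: {}}
  mcari2: {expr: '', bands: {}}
  mtci: {expr: '', bands: {}}
  sipi2: {expr: '', bands: {}}
  tcari: {expr: '', bands: {}}
  ari1: {expr: '', bands: {}}
  ari2: {expr: '', bands: {}}
  cri: {expr: '', bands: {}}
  npci: {expr: '', bands: {}}
  pri2: {expr: '', bands: {}}
  psri: {expr: '', bands: {}}
  wi: {expr: '', bands: {}}
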