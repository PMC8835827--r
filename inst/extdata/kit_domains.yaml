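# Canonical domain map for the KIT cytoplasmic region, construct I516-R946.
# Numbering is the UniProt/author convention.  The TM segment is recorded as
# L525-Y545; the structurally stable TM hint used for kink/bending vectors is
# P524-C537 (boundary conventions for the TM helix differ between sources;
# both are recorded here on purpose).  KID bounds are the complement of the
# rigid-core fit selection (582-688, 769-931) within the TK domain 582-931.
domains:
  TM: "525-545"
  JMR: "546-581"
  JM-P: "546-552"     # T544-D552 in the full receptor; clipped at JMR start
  JM-B: "553-559"
  JM-S: "560-571"
  JM-Z: "572-581"
  NLOBE: "582-680"
  HINGE: "681-688"
  CLOBE: "769-931"
  KID: "689-768"
  ALOOP: "810-839"
  CTAIL: "932-946"
hints:
  TM: "524-537"
  BETA1: "594-597"
  ALPHAC: "637-648"
  ALPHAH1: "701-705"
  ALPHAE: "771-783"
  BETA9: "824-826"
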