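# Residue-range presets for the kinesin-1 motor head on tubulin.
# Each selection is a list of {chain, resno: [from, to], elety} triples;
# chains: K = kinesin, A = alpha-tubulin, B = beta-tubulin.
# These are documented presets, not hard-coded defaults: any selection can
# be replaced by a user file of the same shape.

# Central beta-sheet strands used for the curvature fit (Calpha only);
# excludes the deformable front-end portions of b4/b6/b7.
central_beta_sheet:
  - {chain: K, resno: [11, 15], elety: CA}     # b1
  - {chain: K, resno: [80, 85], elety: CA}     # b3
  - {chain: K, resno: [130, 138], elety: CA}   # b4
  - {chain: K, resno: [142, 144], elety: CA}   # b5
  - {chain: K, resno: [206, 213], elety: CA}   # b6
  - {chain: K, resno: [226, 232], elety: CA}   # b7
  - {chain: K, resno: [296, 302], elety: CA}   # b8

# Rectangular sheet section used for head-orientation axes.
sheet_section:
  - {chain: K, resno: [130, 136], elety: CA}   # b4
  - {chain: K, resno: [206, 212], elety: CA}   # b6
  - {chain: K, resno: [226, 231], elety: CA}   # b7

alpha4:
  - {chain: K, resno: [254, 264], elety: CA}

alpha6:
  - {chain: K, resno: [310, 320], elety: CA}

beta5ab:
  - {chain: K, resno: [155, 157], elety: CA}   # b5a
  - {chain: K, resno: [164, 166], elety: CA}   # b5b

# Tubulin H12 helices used as the alignment reference and triad anchors.
h12_alpha:
  - {chain: A, resno: [417, 432], elety: CA}
h12_beta:
  - {chain: B, resno: [417, 432], elety: CA}

# Reference domains for the interface water-density box.
hydration_reference:
  - {chain: K, resno: [250, 270], elety: CA}   # alpha4 (extended)
  - {chain: A, resno: [395, 420], elety: CA}   # alpha-tubulin H11-H12
  - {chain: B, resno: [425, 435], elety: CA}   # beta-tubulin H12

ploop:
  - {chain: K, resno: [85, 90], elety: CA}

switch1:
  - {chain: K, resno: [190, 204], elety: CA}
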