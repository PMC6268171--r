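# Seven-feature structure-based pharmacophore model of the glyoxalase-1
# (Glo-1) active site with a customized zinc-binder feature. Version 1.
#
# Composition and residue annotations follow the described receptor-ligand
# model: one ZB pointing to the catalytic zinc, two HY filling the
# hydrophobic pocket (Leu92/Phe71/Met179/Leu160/Leu69/Phe62), two HBD
# pointing to Asn103 and Thr101 near the active-site mouth, one HBA toward
# Lys156 and one NI complementary to Arg122/Arg37. Minimum partial match is
# four of the seven features; the ZB feature and the HY feature adjacent to
# it are mandatory in every match.
#
# PROVENANCE: coordinates are SYNTHETIC fixture data emulating the active
# site topology of PDB entry 1QIN (zinc at the bottom of the site, two-ring
# hydrophobic pocket, polar mouth); they are NOT crystallographic and no
# absolute coordinate is meaningful beyond inter-feature geometry.
model:
  name: glo1-zb7
  source_structure: 1QIN
  coordinates: synthetic
  zinc: [0.0, 0.0, 0.0]
  min_required: 4
  mandatory: [ZB1, HY1]
features:
  - id: ZB1
    kind: ZB
    center: [0.0, 0.0, 2.2]
    tolerance: 1.6
    projection: {target: [0.0, 0.0, 0.0], angle_tol: 45.0}
    annotation: "Zn"
  - id: HY1
    kind: HY
    center: [3.8, 1.0, 3.0]
    tolerance: 2.2
    annotation: "hydrophobic pocket (Leu69/Phe62/Leu92)"
  - id: HY2
    kind: HY
    center: [6.5, -1.0, 4.5]
    tolerance: 2.2
    annotation: "hydrophobic pocket (Phe71/Met179/Leu160)"
  - id: HBD1
    kind: HBD
    center: [-3.5, 2.5, 4.0]
    tolerance: 1.6
    projection: {target: [-5.5, 3.5, 4.5], angle_tol: 45.0}
    annotation: "Asn103"
  - id: HBD2
    kind: HBD
    center: [-1.0, 5.0, 4.5]
    tolerance: 1.6
    projection: {target: [-1.5, 7.0, 5.5], angle_tol: 45.0}
    annotation: "Thr101"
  - id: HBA1
    kind: HBA
    center: [2.0, 4.5, 6.0]
    tolerance: 1.6
    projection: {target: [3.0, 6.0, 7.5], angle_tol: 45.0}
    annotation: "Lys156"
  - id: NI1
    kind: NI
    center: [-2.5, -3.5, 5.0]
    tolerance: 1.6
    annotation: "Arg122/Arg37"
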