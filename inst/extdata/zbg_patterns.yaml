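# Zinc-binding-group dictionary, version 1.
#
# Eight allowed classes of zinc-coordinating functional groups; hydroxamates
# and thiols are deliberately excluded despite their well-known zinc
# affinity (poor absorption / metabolic liabilities for hydroxamates, taste
# and photosensitivity issues for thiols). Exclusion patterns veto only
# their own atoms, never the whole molecule: an allowed class elsewhere in
# the same molecule is still reported.
#
# Each class names a matcher interpreted by the detector:
#   ring        - 5-membered conjugated ring whose cyclic element sequence
#                 matches one of `sequences` (rotation/reflection invariant,
#                 hence invariant to the NH tautomer drawn); coordinating
#                 atoms are the pyridine-type ring nitrogens (no hydrogen).
#   carboxyl    - C(=O)O[H or -]; esters do not match; both oxygens
#                 coordinate. Deprotonated carboxylates match.
#   phosphate   - P(=O) bearing at least one free O[H or -]; free acid and
#                 mono/di-esters match; terminal oxygens coordinate.
#   hydroxy_oxo - enol/phenol/olate oxygen on a carbon placed 1,2-adjacent
#                 or peri (two bonds) to a carbonyl carbon, covering
#                 1-hydroxy-2-oxo cores and the flavonoid 4-keto-5-OH
#                 chelation motif; the hydroxyl and carbonyl oxygens
#                 coordinate. Catechols (two hydroxyls, no carbonyl) are
#                 intentionally not covered.
#   hydroxamate - N-O[H/-] on a nitrogen attached to a carbonyl carbon
#                 (forward and reverse hydroxamates).
#   thiol       - S-H sulfur.
#
# SMARTS strings are reference documentation of the intended chemistry.
version: 1
allowed:
  carboxyl:
    matcher: carboxyl
    smarts: "[CX3](=O)[OX2H1,OX1-]"
  phosphate:
    matcher: phosphate
    smarts: "[PX4](=O)([OX2H1,OX1-])"
  imidazole:
    matcher: ring
    sequences: [["N", "C", "N", "C", "C"]]
    smarts: "c1cnc[nH]1"
  triazole-123:
    matcher: ring
    sequences: [["N", "N", "N", "C", "C"]]
    smarts: "c1c[nH]nn1"
  triazole-124:
    matcher: ring
    sequences: [["N", "N", "C", "N", "C"]]
    smarts: "c1nc[nH]n1"
  tetrazole:
    matcher: ring
    sequences: [["N", "N", "N", "N", "C"]]
    smarts: "c1nnn[nH]1"
  thiadiazole:
    matcher: ring
    # both the 1,3,4- and 1,2,5-isomers are accepted
    sequences: [["S", "C", "N", "N", "C"], ["S", "N", "C", "C", "N"]]
    smarts: "c1nncs1"
  hydroxy-oxo-12:
    matcher: hydroxy_oxo
    smarts: "[OX2H1,OX1-][#6]~[#6]C=O"
excluded:
  hydroxamate:
    matcher: hydroxamate
    smarts: "[OX2H1,OX1-][NX3]C=O"
  thiol:
    matcher: thiol
    smarts: "[SX2H1]"
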