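---
title: "Zinc-binder-aware pharmacophore screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zinc-binder-aware pharmacophore screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zbscreen)
```

## The problem

Glyoxalase-1 (Glo-1) is a zinc metalloenzyme that detoxifies methylglyoxal;
inhibiting it selectively kills metabolically overactive tumour cells.
Its active site has three functional regions: the catalytic zinc at the
bottom, a small hydrophobic pocket that tolerates up to two aromatic rings
(Leu92/Phe71/Met179/Leu160/Leu69/Phe62), and a polar mouth
(Arg122/Arg37/Lys150/Lys156). Any credible inhibitor must coordinate the
zinc, so a screening protocol for this target has to reason explicitly about
*zinc-binding groups* (ZBGs) — something generic pharmacophore perception
does not do, because standard feature dictionaries type a zinc interaction
as an ordinary hydrogen-bond donor.

`zbscreen` implements the complete funnel: 2D fingerprint similarity search
against a compound library, drug-likeness and ADMET filtration, ligand form
enumeration at physiological pH, 3D pharmacophore screening with a custom
zinc-binder feature restricted to a curated ZBG chemistry, and consensus
aggregation of external docking scores.

## Fingerprints and similarity measures

Circular environments are grown iteratively around each atom up to a
topological diameter of 6 (three growth rounds) and hashed into sparse
feature multisets. Two atom abstractions are available:

* **functional-class** — atoms are seeded with pharmacophoric flags
  (donor, acceptor, positively/negatively ionizable, aromatic, halogen);
  duplicate features are removed (bit semantics);
* **atom-type** — atoms are seeded with element, charge, a hybridization
  proxy and degree; duplicate features are counted (count semantics).

Similarity between a target and a reference is computed from SA (features
in both), SB (target only) and SC (reference only):

| measure  | formula                         |
|----------|---------------------------------|
| Tanimoto | SA / (SA + SB + SC)             |
| Dice     | 2·SA / (2·SA + SB + SC)         |
| Cosine   | SA / sqrt((SA + SB)·(SA + SC))  |

Dice equals 2T/(1+T) and the Cosine is bounded below by the Tanimoto via
the arithmetic–geometric mean inequality; the test suite asserts both
orderings on randomized components. The environment hash is a fixed
31-bit polynomial scheme; collisions are possible and tolerated — the
contract is determinism within the package, not compatibility with any
external fingerprint implementation. Whether count or bit semantics is
"correct" for a given study is genuinely open, so both modes are exposed
and the defaults follow the duplicate-handling conventions above.

```{r similarity}
mols <- parse_smiles(c("CCO", "CCCO"), c("ethanol", "propanol"))
fp <- lapply(mols, fingerprint, scheme = "atom-type")
comp <- fp_components(fp[[1]], fp[[2]])
c(tanimoto = fp_similarity(comp, "tanimoto"),
  dice = fp_similarity(comp, "dice"),
  cosine = fp_similarity(comp, "cosine"))
```

A screening battery runs one top-k search per (reference × measure ×
scheme); with five references, three measures, two schemes and k = 500
against a database of at least 500 molecules, the merged pre-deduplication
hit list has exactly 15,000 rows. Ties at the k-boundary are broken stably
by database input order, for reproducibility.

## Drug-likeness and ADMET filtration

The Lipinski/Veber filter applies six rules: HBD ≤ 5, HBA ≤ 10, clogP ≤ 5,
MW < 500 (this one strict), rotatable bonds ≤ 10, TPSA ≤ 140 Å². Donors and
acceptors use the Lipinski convention (N–H/O–H hydrogens; N+O atom count),
which is deliberately distinct from the geometric donor/acceptor perception
of the pharmacophore engine. The default tolerates zero violations —
strict selection. logP and TPSA come from Open Babel's published
atom-contribution schemes; molecular weight is summed from standard atomic
masses including implicit hydrogens.

The ADMET stage uses fixed rule-based proxies for the three filter
dimensions: solubility (clogP ≤ 6), passive intestinal absorption
(Egan-style: TPSA ≤ 131.6 Å² and clogP ≤ 5.88), and a blood–brain-barrier
window (TPSA ≤ 90 Å² and 1 ≤ clogP ≤ 4) that is reported as a flag but is
not exclusionary by default, since a peripheral anti-cancer target does not
require CNS penetration. These surrogates are transparent, versioned
constants, not fitted models; they keep the funnel testable and honest
about what it can claim.

## Ligand preparation

`enumerate_forms()` expands each survivor into the chemical forms it
populates at physiological pH (6.5–8.5):

* **ionization** from a versioned pKa rule table
  (`inst/extdata/pka_rules.yaml`): a group is toggled when its literature
  pKa lies within the window widened by ±2 units, so acetic acid
  (pKa 4.76) yields the carboxylate, an aliphatic amine (pKa 10.64) the
  ammonium form;
* **tautomers** from a curated transform list — lactam/lactim, azole NH
  shift, 1,3-keto-enol on dicarbonyls. The azole shift matters most here:
  which tetrazole or imidazole nitrogen carries the hydrogen changes which
  nitrogens present lone pairs to the zinc;
* **stereoisomers** for unassigned stereocentres, capped at 2⁴ centres.

Enumeration is the only funnel stage allowed to increase the record count.
Deduplication keys on Open Babel canonical SMILES (charges included) plus
any assigned stereo labels, keeps the first occurrence, and is idempotent.

## The zinc-binding-group dictionary

The dictionary (`inst/extdata/zbg_patterns.yaml`, version 1) admits eight
classes: carboxyl, phosphate, imidazole, 1,2,3-triazole, 1,2,4-triazole,
tetrazole, thiadiazole (1,3,4- and 1,2,5-isomers), and 1-hydroxy-2-oxo
derivatives (covering the flavonoid 4-keto-5-OH chelation motif).
Hydroxamates and thiols — classic ZBGs — are deliberately excluded on
pharmacokinetic and toxicity grounds (poor absorption, glucuronidation and
potentially mutagenic hydroxylamine metabolites for hydroxamates; taste
disturbance and photosensitivity for thiols). Exclusion is atom-scoped: a
thiol group vetoes only its own atoms, so a molecule carrying both a thiol
and a carboxylate still reports the carboxylate.

Azole classes are matched as 5-membered conjugated rings by cyclic element
sequence, up to rotation and reflection — which makes detection invariant
to the NH tautomer drawn. Coordinating atoms are the pyridine-type ring
nitrogens; for the oxygen classes, the carbonyl/hydroxyl or acid oxygens.
The ring sequences, class list and exclusions are data; the detector
interprets them. (No installed substructure engine exposes matched atom
indices, which `ZbgMatch` requires, so the matcher is implemented in the
package against the same pattern file.)

The bidentate chelation check `chelation_geometry_ok()` encodes the
structure–activity observation that the flavonoid ketone and hydroxyl
oxygens must be 2.5 ± 0.5 Å apart: the accepted window is exactly
[2.0, 3.0] Å, both bounds inclusive.

```{r zbg}
hits <- detect_zbg(parse_smiles("OC(=O)CCS", "mercapto_acid")[[1]])
vapply(hits, `[[`, character(1), "class")   # thiol vetoed, carboxyl kept
```

## The pharmacophore engine

A model is a set of typed, toleranced spheres (HBA, HBD, HY, NI, PI, RA,
ZB), optionally directional, with a minimum match count and a mandatory
subset. The packaged Glo-1 model has seven features — ZB pointing to the
zinc, two HY in the pocket, two HBD toward Asn103/Thr101, one HBA toward
Lys156, one NI complementary to Arg122/Arg37 — with `min_required = 4` and
mandatory {ZB, adjacent HY}. "Adjacent" is resolved as the HY feature whose
centre is nearest the ZB centre. Feature tolerances default to 1.6 Å
(2.2 Å for HY), common pharmacophore practice. The model file's
coordinates are *synthetic* fixture data emulating the described active-site
topology; no crystallographic coordinates ship with the package, and tests
assert composition, never absolute positions.

Matching enumerates kind-compatible assignments of perceived ligand points
to model features (a ZB feature accepts only ZB points, every other kind
its own), requires all mandatory features plus at least `min_required`
mapped (never fewer than three — the minimum for a determined rigid
superposition), superposes each candidate assignment by least squares
(Kabsch), and accepts it when every mapped displacement stays within its
feature's tolerance. The fit value is

fit = Σ over mapped features (1 − displacement / tolerance),

a transparent surrogate in [0, mapped count]: a perfect five-feature map
scores exactly 5.0. Ties are broken by larger mapped count, then
lexicographically. On small point sets the matcher is provably equivalent
to an exhaustive assignment/rotation-search oracle (asserted to 10⁻³ in
the tests), and every returned match re-verifies its own displacements and
fit from the stored transform to 10⁻⁹.

Receptor–ligand perception (`perceive_complex_pharmacophore()`) derives
features from geometric rules — hydrogen bond at ≤ 3.5 Å with a ≥ 120°
donor angle, hydrophobic contact at ≤ 4.5 Å between apolar carbons, charge
pair at ≤ 5.5 Å, zinc coordination for ligand N/O at ≤ 2.8 Å. The zinc
interaction is first typed as a donor candidate (that is what generic
perception would do); `customize_zb()` then re-types the single
zinc-oriented donor to ZB, retaining position and tolerance — the operation
is idempotent and errors when nothing orients to the zinc. Zinc-coordinating
ligand atoms are excluded from ordinary hydrogen-bond perception, since
the committed lone pair cannot also count as a generic donor.

## Conformers

Screening embeds up to `max_confs` conformers per molecule (the protocol
default is 255 with a 20 kcal/mol energy window) and keeps the best match
across the surviving ensemble. Coordinates come from a deterministic
coarse breadth-first builder with standard bond lengths; additional
conformers are sampled by seeded torsion rotation about rotatable bonds.
Conformer energies are a documented steric surrogate — a soft-sphere
clash penalty, E = 10·Σ(3.2 − d)² kcal/mol over non-bonded pairs closer
than 3.2 Å — and the energy window applies to that estimate. This builder
is intentionally crude: it trades geometric realism for strict seed
reproducibility, which the funnel's determinism guarantees require.
Non-deterministic external 3D builders would break byte-identical reports.

## Consensus scoring

Docking itself is out of scope; the module ingests score tables
(candidate, pose, score name, value) for the six functions GoldScore,
ChemScore, ASP, CHEMPLP, CDOCKER and LibDock. The direction map is
explicit configuration: the GOLD fitness functions and LibDock are
higher-better, CDOCKER interaction energies lower-better and negated
before raw summation. `raw_sum` sums the sign-normalized best-pose values;
`rank_sum` sums per-score ranks and is invariant under any strictly
monotone rescaling of a single score. Candidates missing any function are
excluded rather than imputed. The final report joins consensus rank with
pharmacophore fit so the two selection axes can be compared side by side.

## Synthetic study conditions

The generators in this package define the conditions under which the
funnel is tested:

* `synth_library(n, seed, zbg_fraction = 0.35, violation_fraction = 0.1,
  excluded_fraction = 0.05)` assembles molecules from a fragment grammar
  (six ring scaffolds × six linkers × substituents), cycling the
  ZBG-bearing share through all eight allowed classes and engineering the
  violator share to break at least one Lipinski/Veber rule. The default
  fractions are a deliberately generous ZBG prevalence — real vendor
  libraries carry far fewer metal binders — chosen so that every class is
  exercised at test-scale n.
* `toy_conformer(model, k, jitter, seed)` builds feature skeletons:
  disconnected pseudo-ligand fragments (tetrazole ring for ZB, propane for
  HY, hydroxyl for HBD, ether for HBA, sulfonate for NI) placed within
  `jitter` of exactly k chosen feature centres, mandatory-first. Because
  the model's features are ≥ 3.5 Å apart and tolerances ≤ 2.2 Å, the
  intended subset is exact ground truth.
* `mini_complex(seed)` emits a ~11-atom receptor fragment (zinc, a
  backbone acceptor, a leucine side chain) and a six-atom ligand realizing
  exactly one zinc coordination, one hydrogen bond and one hydrophobic
  contact.
* `synth_score_table(candidates, seed)` draws plausible score ranges with
  a designated candidate dominating all six functions.

What passing these tests shows — and does not show. The generators
guarantee that every rule, formula and invariant behaves exactly as
documented on inputs with known ground truth. They do not emulate the
property distribution of a real vendor database: the fragment grammar's
diversity is limited (a large similarity hit list collapses heavily at
deduplication), the crude embedder under-predicts real conformer
geometries, and absolute screening enrichment on real libraries is
therefore out of reach of these tests.

## Problem sizes and numerical choices

The shipped test suite runs the funnel at library sizes 60–520 with
reduced conformer counts (2–4), plus one full 10,000-molecule end-to-end
run with k = 500 that reproduces the 15,000-row merged battery; these
sizes keep the whole suite in the minutes range on a single CPU while
still exercising every stage at its documented arithmetic. Tolerances:
match re-verification to 1e-9, matcher-vs-oracle agreement to 1e-3
(limited by the oracle's numerical rotation search), rigid-invariance of
fit to 1e-6. Degenerate inputs are defined, not errors: empty molecules
fingerprint to empty maps with a warning, empty-vs-empty similarity is 0
by convention, an empty database yields an empty hit list, an empty
library runs the funnel to completion with zero counts.

## Known limitations

* Descriptor absolute values (logP, TPSA) follow Open Babel's
  implementations and will differ from proprietary descriptor engines;
  filter *boundaries* are exact, filter *inputs* are estimator-dependent.
* The packaged Glo-1 model's coordinates are synthetic; only its
  composition, annotations and matching semantics are asserted.
* The fit value is this package's documented surrogate; it is monotone in
  displacement like commercial fit scores but not numerically comparable
  to them.
* Aromaticity perception is Hückel-style on 5/6-rings of the kekulized
  graph; exotic ring systems may be typed conservatively.
* The conformer builder optimizes reproducibility, not strain energies;
  screening recall on real flexible molecules would require a proper
  force-field embedder upstream, with the matcher unchanged.
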