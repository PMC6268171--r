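# Deterministic synthetic generators for every input the funnel consumes:
# a drug-like library with controllable ZBG and rule-violation fractions,
# toy conformers engineered to match exactly k model features, a miniature
# zinc-site receptor complex with known interactions, and docking score
# tables. All are pure functions of their arguments (seed included); toy
# conformers are feature skeletons - pseudo-ligand fragments carrying the
# right perception signatures at engineered positions - rather than
# realistic molecules, which makes k-feature ground truth exact.

ZBG_SUBSTITUENTS <- c(
  carboxyl = "C(=O)O",
  phosphate = "OP(=O)(O)O",
  imidazole = "c1cnc[nH]1",
  `triazole-123` = "c1c[nH]nn1",
  `triazole-124` = "c1nc[nH]n1",
  tetrazole = "c1nnn[nH]1",
  thiadiazole = "c1nncs1",
  `hydroxy-oxo-12` = "C(=O)c1ccccc1O"
)

EXCLUDED_SUBSTITUENTS <- c(hydroxamate = "C(=O)NO", thiol = "S")

SYNTH_SCAFFOLDS <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "c1ccc2ccccc2c1",
                     "C1CCNCC1", "c1ccsc1")
SYNTH_LINKERS <- c("", "C", "CC", "CCC", "OC", "CN")
SYNTH_PLAIN <- c("C", "CC", "O", "OC", "N", "C(C)C", "Cl", "F", "C(=O)N")
SYNTH_VIOLATORS <- c(
  "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",                    # MW/logP/rotb
  "C(O)C(O)C(O)C(O)C(O)C(O)C(O)O",                     # HBD > 5
  "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC"               # heavier still
)

#' Generate a synthetic drug-like screening library
#'
#' Molecules are assembled from a fragment grammar (ring scaffold x linker x
#' substituent). A `zbg_fraction` share carries exactly one allowed
#' zinc-binding-group class (cycled over all eight), a disjoint `excluded_fraction`
#' share carries a hydroxamate or thiol instead, and a `violation_fraction`
#' share is engineered to violate at least one Lipinski/Veber rule.
#'
#' @param n library size.
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param zbg_fraction share of ZBG-bearing molecules (default 0.35).
#' @param violation_fraction share of rule violators (default 0.1).
#' @param excluded_fraction share carrying an excluded group (default 0.05).
#' @return list of `mol_record` with attribute `labels`: data.frame
#'   (id, smiles, zbg_class, excluded_group, violates).
#' @export
synth_library <- function(n, seed = 1L, zbg_fraction = 0.35,
                          violation_fraction = 0.1,
                          excluded_fraction = 0.05) {
  if (n == 0) {
    out <- list()
    attr(out, "labels") <- data.frame(id = character(0), smiles = character(0),
                                      zbg_class = character(0),
                                      excluded_group = character(0),
                                      violates = logical(0))
    return(out)
  }
  n_zbg <- round(n * zbg_fraction)
  n_exc <- min(round(n * excluded_fraction), n - n_zbg)
  n_vio <- min(round(n * violation_fraction), n - n_zbg - n_exc)
  role <- c(rep("zbg", n_zbg), rep("excluded", n_exc), rep("violator", n_vio),
            rep("plain", n - n_zbg - n_exc - n_vio))
  labels <- data.frame(id = sprintf("syn%05d", seq_len(n)),
                       smiles = character(n), zbg_class = NA_character_,
                       excluded_group = NA_character_, violates = FALSE)
  with_local_seed(seed, {
    for (i in seq_len(n)) {
      scaf <- sample(SYNTH_SCAFFOLDS, 1)
      link <- sample(SYNTH_LINKERS, 1)
      smi <- switch(role[i],
        zbg = {
          cls <- names(ZBG_SUBSTITUENTS)[(i - 1L) %% 8L + 1L]
          labels$zbg_class[i] <- cls
          paste0(scaf, link, ZBG_SUBSTITUENTS[[cls]])
        },
        excluded = {
          grp <- names(EXCLUDED_SUBSTITUENTS)[(i %% 2L) + 1L]
          labels$excluded_group[i] <- grp
          paste0(scaf, "C", EXCLUDED_SUBSTITUENTS[[grp]])
        },
        violator = {
          labels$violates[i] <- TRUE
          paste0(scaf, sample(SYNTH_VIOLATORS, 1))
        },
        paste0(scaf, link, sample(SYNTH_PLAIN, 1)))
      labels$smiles[i] <- smi
    }
  })
  mols <- parse_smiles(labels$smiles, labels$id)
  attr(mols, "labels") <- labels
  mols
}

#' Build a toy conformer matching exactly k model features
#'
#' Places pseudo-ligand fragments (tetrazole ring for ZB, propane for HY,
#' hydroxyl oxygen for HBD, ether oxygen for HBA, sulfonate for NI, benzene
#' for RA, ammonium nitrogen for PI) so that the perceived feature points
#' sit within `jitter` of exactly `k` chosen feature centres
#' (mandatory-first) and outside tolerance of all others.
#'
#' @param model `ph_model`.
#' @param k number of features to satisfy (0..feature count); when
#'   `k >= 2` the mandatory features are always included.
#' @param jitter placement noise in Angstrom (default 0).
#' @param seed RNG seed for the jitter directions.
#' @return `mol_record` with 3D coordinates and attribute `intended`
#'   (the ids of the satisfied features).
#' @export
toy_conformer <- function(model, k, jitter = 0, seed = 1L) {
  ids <- feature_ids(model)
  if (k > length(ids)) stop("k exceeds the model feature count")
  mand <- model$mandatory
  chosen <- if (k >= 2) c(mand, setdiff(ids, mand))[seq_len(k)]
            else ids[seq_len(k)]
  atoms <- data.frame(element = character(0), charge = integer(0))
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  coords <- matrix(0, 0, 3)
  add_frag <- function(el, ch, bnd, xyz) {
    off <- nrow(atoms)
    atoms <<- rbind(atoms, data.frame(element = el, charge = ch))
    if (nrow(bnd))
      bonds <<- rbind(bonds, data.frame(a1 = bnd[, 1] + off,
                                        a2 = bnd[, 2] + off,
                                        order = bnd[, 3]))
    coords <<- rbind(coords, xyz)
  }
  pentagon <- function(r = 1.13) t(vapply(0:4, function(i)
    c(r * cos(2 * pi * i / 5), r * sin(2 * pi * i / 5), 0), numeric(3)))
  with_local_seed(seed, {
    for (fi in seq_along(model$features)) {
      f <- model$features[[fi]]
      if (!(f$id %in% chosen)) next
      dirn <- stats::rnorm(3); dirn <- dirn / vnorm(dirn)
      target <- f$center + dirn * jitter
      switch(f$kind,
        ZB = {
          # 1H-tetrazole ring: C1, N2(H), N3, N4, N5; coordinating = N3,N4,N5
          ring <- pentagon()
          coord_cent <- colMeans(ring[3:5, ])
          ring <- sweep(ring, 2, coord_cent)          # centre coordinating N
          ring <- sweep(ring, 2, target, `+`)
          add_frag(c("C", "N", "N", "N", "N"), rep(0L, 5),
                   cbind(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 1),
                         c(1, 1, 2, 1, 2)), ring)
        },
        HY = {
          ch3 <- rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0))
          add_frag(rep("C", 3), rep(0L, 3),
                   cbind(c(1, 2), c(2, 3), c(1, 1)),
                   sweep(ch3, 2, target, `+`))
        },
        HBD = add_frag("O", 0L, matrix(0, 0, 3), matrix(target, 1, 3)),
        HBA = {
          eth <- rbind(c(-1.4, 0, 0), c(0, 0, 0), c(1.4, 0, 0))
          add_frag(c("C", "O", "C"), rep(0L, 3),
                   cbind(c(1, 2), c(2, 3), c(1, 1)),
                   sweep(sweep(eth, 2, eth[2, ]), 2, target, `+`))
        },
        NI = {
          # methanesulfonate; NI point = centroid of S + three oxygens
          frag <- rbind(c(-1.8, 0, 0), c(0, 0, 0), c(0.7, 1.2, 0),
                        c(0.7, -1.2, 0), c(-0.1, 0, 1.4))
          cen <- colMeans(frag[2:5, ])
          add_frag(c("C", "S", "O", "O", "O"), c(0L, 0L, 0L, 0L, -1L),
                   cbind(c(1, 2, 2, 2), c(2, 3, 4, 5), c(1, 2, 2, 1)),
                   sweep(sweep(frag, 2, cen), 2, target, `+`))
        },
        RA = {
          hexv <- t(vapply(0:5, function(i)
            c(1.39 * cos(pi * i / 3), 1.39 * sin(pi * i / 3), 0), numeric(3)))
          add_frag(rep("C", 6), rep(0L, 6),
                   cbind(1:6, c(2:6, 1), rep(c(2, 1), 3)),
                   sweep(hexv, 2, target, `+`))
        },
        PI = add_frag("N", 1L, matrix(0, 0, 3), matrix(target, 1, 3)))
    }
  })
  out <- mol_record(sprintf("toy_k%d", k), atoms, bonds, coords,
                    source = "toy_conformer")
  attr(out, "intended") <- chosen
  out
}

#' Generate a miniature zinc-site receptor-ligand complex
#'
#' A ~20-atom receptor fragment (zinc ion, a glycine backbone oxygen as
#' hydrogen-bond acceptor, a leucine side chain as hydrophobic patch, plus
#' zinc-coordinating residue atoms) with a small ligand placed to realize
#' exactly three interactions: one zinc coordination (ligand hydroxyl O at
#' 2.1 A from Zn), one hydrogen bond (ligand hydroxyl to the backbone O at
#' 2.9 A, donor angle ~150 degrees) and one hydrophobic contact.
#'
#' @param seed deterministic jitter seed (coordinates are perturbed by up to
#'   0.02 A without breaking any rule).
#' @return list with `receptor_pdb` (path to a written PDB file), `ligand`
#'   (`mol_record` with coords), `zinc` (xyz), `ground_truth` (data.frame of
#'   expected interactions).
#' @export
mini_complex <- function(seed = 1L) {
  jit <- with_local_seed(seed, matrix(stats::runif(3 * 3, -0.02, 0.02), 3, 3))
  zn <- c(0, 0, 0)
  # receptor atoms: label, resid, resno, xyz
  rec <- rbind(
    data.frame(elety = "ZN", resid = "ZN", resno = 200, x = 0, y = 0, z = 0),
    data.frame(elety = "OE1", resid = "GLU", resno = 99, x = 0, y = 0, z = -2.0),
    data.frame(elety = "NE2", resid = "HIS", resno = 126, x = -2.0, y = 0.8, z = -0.6),
    data.frame(elety = "O", resid = "GLY", resno = 10, x = 8.0, y = 3.0, z = 1.0),
    data.frame(elety = "C", resid = "GLY", resno = 10, x = 9.2, y = 3.4, z = 1.4),
    data.frame(elety = "CA", resid = "GLY", resno = 10, x = 10.4, y = 2.6, z = 1.0),
    data.frame(elety = "N", resid = "GLY", resno = 10, x = 10.6, y = 1.4, z = 0.4),
    data.frame(elety = "CB", resid = "LEU", resno = 92, x = 3.0, y = -4.0, z = 2.0),
    data.frame(elety = "CG", resid = "LEU", resno = 92, x = 4.2, y = -4.6, z = 2.6),
    data.frame(elety = "CD1", resid = "LEU", resno = 92, x = 5.4, y = -4.0, z = 2.0),
    data.frame(elety = "CD2", resid = "LEU", resno = 92, x = 4.2, y = -6.1, z = 2.4)
  )
  rec[2:4, c("x", "y", "z")] <- rec[2:4, c("x", "y", "z")] + jit
  # ligand: HO1-C2(-C3H2-C4H3 toward the pocket) ... O5H donor to GLY10 O
  #   O1 at 2.1 A from Zn (coordination); O5 2.9 A from GLY10 O;
  #   C3/C4 within 4.5 A of LEU92 side-chain carbons.
  lig_xyz <- rbind(
    c(0.0, 0.0, 2.1),     # O1 (hydroxyl, zinc-coordinating)
    c(1.2, -0.6, 2.7),    # C2
    c(2.5, -1.7, 2.7),    # C3 wait - adjust toward pocket
    c(3.6, -2.5, 3.0),    # C4
    c(3.9, 3.0, 3.6),     # C5 linker toward the mouth
    c(5.55, 3.0, 2.55)    # O5 (hydroxyl donor, ~2.9 A from GLY10 O, linear)
  )
  lig <- mol_record("minilig",
                    data.frame(element = c("O", "C", "C", "C", "C", "O"),
                               charge = 0L),
                    data.frame(a1 = c(1, 2, 3, 2, 5),
                               a2 = c(2, 3, 4, 5, 6),
                               order = 1L),
                    coords = lig_xyz, source = "mini_complex")
  pdb_path <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = pdb_path,
                   xyz = as.numeric(t(as.matrix(rec[, c("x", "y", "z")]))),
                   resno = rec$resno, resid = rec$resid,
                   eleno = seq_len(nrow(rec)), elety = rec$elety,
                   chain = rep("A", nrow(rec)))
  gt <- data.frame(
    kind = c("HBD", "HBD", "HY"),
    partner = c("Zn", "GLY10", "LEU92"),
    note = c("zinc coordination (O1, 2.1 A)",
             "hydrogen bond (O5 to backbone O, 2.9 A)",
             "hydrophobic contact (C3-C4 patch)"))
  list(receptor_pdb = pdb_path, ligand = lig, zinc = zn, ground_truth = gt)
}

#' Generate a synthetic docking score table
#'
#' All six score functions (GoldScore, ChemScore, ASP, CHEMPLP, CDOCKER,
#' LibDock) for every candidate, two poses each, drawn from plausible ranges
#' (GOLD fitness 20-80, CDOCKER -60-0, LibDock 50-150). The first candidate
#' (the "plant") dominates on all six functions.
#'
#' @param candidates character vector of candidate ids.
#' @param seed RNG seed.
#' @return data.frame (candidate_id, pose_id, score_name, value) with
#'   attribute `plant` naming the dominating candidate.
#' @export
synth_score_table <- function(candidates, seed = 1L) {
  if (!length(candidates)) stop("candidate id list must be non-empty")
  ranges <- list(GoldScore = c(20, 70), ChemScore = c(20, 70),
                 ASP = c(20, 70), CHEMPLP = c(20, 70),
                 CDOCKER = c(-55, -5), LibDock = c(50, 140))
  rows <- list()
  with_local_seed(seed, {
    for (cid in candidates) for (sn in names(SCORE_DIRECTIONS)) {
      rg <- ranges[[sn]]
      vals <- round(stats::runif(2, rg[1], rg[2]), 2)
      if (cid == candidates[1]) {
        # the plant dominates: best edge of the range, direction-aware
        vals <- if (SCORE_DIRECTIONS[[sn]] > 0) rg[2] + c(5, 2)
                else rg[1] - c(5, 2)
      }
      rows[[length(rows) + 1]] <- data.frame(
        candidate_id = cid, pose_id = paste0("pose", 1:2),
        score_name = sn, value = vals)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "plant") <- candidates[1]
  out
}
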