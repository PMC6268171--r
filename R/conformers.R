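# Deterministic conformer generation for pharmacophore screening.
#
# Coordinates are built by a coarse breadth-first placement with standard
# bond lengths and tetrahedral/trigonal direction templates (rings come out
# distorted but topologically coherent); additional conformers are sampled
# by seeded torsion rotation about rotatable bonds. Conformer energies are
# a documented steric surrogate: a soft-sphere clash penalty in kcal/mol
# units, E = 10 * sum over nonbonded pairs closer than 3.2 A of
# (3.2 - d)^2. The screening energy window applies to this estimate.
# Everything is a pure function of (molecule, seed); the package
# deliberately avoids non-reproducible external 3D builders.

BOND_LENGTH <- 1.5

# deterministic coarse 3D embedding of a molecular graph
embed_3d <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0) return(matrix(0, 0, 3))
  adj <- mol_adj(mol)
  xyz <- matrix(NA_real_, n, 3)
  dirs <- rbind(c(1, 0, 0), c(-0.333, 0.943, 0), c(-0.333, -0.471, 0.816),
                c(-0.333, -0.471, -0.816), c(0.5, 0.866, 0), c(0.5, -0.866, 0),
                c(-1, 0, 0), c(0, 0, 1))
  placed <- logical(n)
  offset <- c(0, 0, 0)
  for (root in seq_len(n)) {
    if (placed[root]) next
    xyz[root, ] <- offset
    placed[root] <- TRUE
    q <- root
    while (length(q)) {
      a <- q[1]; q <- q[-1]
      used <- 0L
      parent_dir <- NULL
      pl <- adj[[a]]$nbr[placed[adj[[a]]$nbr]]
      if (length(pl)) parent_dir <- xyz[a, ] - xyz[pl[1], ]
      for (b in adj[[a]]$nbr) {
        if (placed[b]) next
        used <- used + 1L
        base <- dirs[(used - 1L) %% nrow(dirs) + 1L, ]
        d <- if (!is.null(parent_dir) && vnorm(parent_dir) > 1e-6) {
          # bias away from the parent to approximate valence angles
          v <- base - parent_dir / vnorm(parent_dir) * 0.5
          v / vnorm(v)
        } else base
        # spread: perturb deterministically by atom index to avoid overlaps
        jit <- c(sin(b * 1.7), cos(b * 2.3), sin(b * 0.9)) * 0.25
        d <- d + jit; d <- d / vnorm(d)
        xyz[b, ] <- xyz[a, ] + d * BOND_LENGTH
        placed[b] <- TRUE
        q <- c(q, b)
      }
    }
    offset <- offset + c(6, 0, 0)   # next fragment well separated
  }
  xyz
}

# rotatable bonds as (a1, a2) rows; same convention as count_rotatable
rotatable_bonds <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(matrix(integer(0), 0, 2))
  deg <- heavy_degree(mol)
  rings <- mol_rings(mol)
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    if (b$order[i] != 1L) next
    a1 <- b$a1[i]; a2 <- b$a2[i]
    if (deg[a1] < 2 || deg[a2] < 2) next
    if (any(vapply(rings, function(r) a1 %in% r && a2 %in% r, logical(1)))) next
    keep[i] <- TRUE
  }
  cbind(b$a1[keep], b$a2[keep])
}

# atoms on the a2 side of bond a1-a2
bond_subtree <- function(mol, a1, a2) {
  adj <- mol_adj(mol)
  seen <- c(a1, a2)
  q <- a2
  while (length(q)) {
    a <- q[1]; q <- q[-1]
    for (nb in adj[[a]]$nbr) if (!(nb %in% seen)) { seen <- c(seen, nb); q <- c(q, nb) }
  }
  setdiff(seen, a1)
}

rotate_about_bond <- function(xyz, a1, a2, subtree, angle) {
  axis <- xyz[a2, ] - xyz[a1, ]
  nrm <- vnorm(axis)
  if (nrm < 1e-9) return(xyz)
  u <- axis / nrm
  ca <- cos(angle); sa <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) * ca + sa * K + (1 - ca) * (u %o% u)
  mov <- setdiff(subtree, a2)
  if (length(mov))
    xyz[mov, ] <- sweep(t(R %*% t(sweep(xyz[mov, , drop = FALSE], 2,
                                        xyz[a2, ]))), 2, xyz[a2, ], `+`)
  xyz
}

# soft-sphere steric energy (kcal/mol surrogate)
steric_energy <- function(mol, xyz) {
  n <- nrow(xyz)
  if (n < 4) return(0)
  bonded <- matrix(FALSE, n, n)
  b <- mol$bonds
  if (nrow(b)) for (i in seq_len(nrow(b))) {
    bonded[b$a1[i], b$a2[i]] <- TRUE; bonded[b$a2[i], b$a1[i]] <- TRUE
  }
  onethree <- bonded %*% bonded > 0
  dd <- as.matrix(stats::dist(xyz))
  mask <- upper.tri(dd) & !bonded & !onethree
  close <- mask & dd < 3.2
  10 * sum((3.2 - dd[close])^2)
}

#' Generate a deterministic conformer ensemble
#'
#' Embeds the molecule (or reuses its own 3D coordinates when present as
#' conformer 1) and samples up to `max_confs - 1` further conformers by
#' seeded torsion rotation; conformers more than `energy_window` kcal/mol
#' above the ensemble minimum of the steric surrogate energy are discarded.
#'
#' @param mol a `mol_record`.
#' @param max_confs maximum conformers generated (default 255).
#' @param energy_window energy threshold above the minimum (default 20).
#' @param seed RNG seed.
#' @return list with `conformers` (list of coordinate matrices), `energies`,
#'   `generated` (count before energy filtering).
#' @export
embed_conformers <- function(mol, max_confs = 255L, energy_window = 20,
                             seed = 1L) {
  base <- if (!is.null(mol$coords)) mol$coords else embed_3d(mol)
  rb <- rotatable_bonds(mol)
  confs <- list(base)
  if (nrow(rb) > 0 && max_confs > 1) {
    subtrees <- lapply(seq_len(nrow(rb)), function(i)
      bond_subtree(mol, rb[i, 1], rb[i, 2]))
    with_local_seed(seed, {
      for (j in seq_len(max_confs - 1L)) {
        xyz <- base
        angles <- stats::runif(nrow(rb), 0, 2 * pi)
        for (i in seq_len(nrow(rb)))
          xyz <- rotate_about_bond(xyz, rb[i, 1], rb[i, 2], subtrees[[i]],
                                   angles[i])
        confs[[length(confs) + 1]] <- xyz
      }
    })
  }
  generated <- length(confs)
  energies <- vapply(confs, function(x) steric_energy(mol, x), numeric(1))
  keep <- energies <= min(energies) + energy_window
  list(conformers = confs[keep], energies = energies[keep],
       generated = generated)
}

#' Pharmacophore screen of a compound library
#'
#' Per molecule: generate up to `max_confs` conformers (deterministic under
#' `seed`), drop conformers above the energy window, perceive feature
#' points, match every conformer against the model and keep the best
#' accepted match. Hits are sorted by fit descending.
#'
#' @param library list of `mol_record`.
#' @param model `ph_model`.
#' @param max_confs conformers per molecule (default 255).
#' @param energy_window kcal/mol above the per-molecule minimum (default 20).
#' @param seed master seed; per-molecule seeds are derived from it.
#' @return list with `hits` (data.frame: id, conformer, mapped, fit,
#'   features) and `counts` (input, embedded, conformers, matched, skipped).
#' @export
ph_screen <- function(library, model, max_confs = 255L, energy_window = 20,
                      seed = 1L) {
  hits <- list()
  counts <- list(input = length(library), embedded = 0L, conformers = 0L,
                 matched = 0L, skipped = 0L)
  for (mol in library) {
    ens <- tryCatch(embed_conformers(mol, max_confs, energy_window,
                                     derive_seed(seed, mol$id)),
                    error = function(e) NULL)
    if (is.null(ens) || !length(ens$conformers)) {
      counts$skipped <- counts$skipped + 1L
      warning("embedding failed for '", mol$id, "': skipped", call. = FALSE)
      next
    }
    counts$embedded <- counts$embedded + 1L
    counts$conformers <- counts$conformers + length(ens$conformers)
    best <- NULL
    for (ci in seq_along(ens$conformers)) {
      conf <- mol
      conf$coords <- ens$conformers[[ci]]
      pts <- perceive_ligand_features(conf)
      if (!length(pts)) next
      m <- ph_match_points(pts, model, sprintf("%s/c%d", mol$id, ci))
      if (!is.null(m) && (is.null(best) || m$fit > best$fit)) best <- m
    }
    if (!is.null(best)) {
      counts$matched <- counts$matched + 1L
      hits[[length(hits) + 1]] <- data.frame(
        id = mol$id, conformer = best$conformer, mapped = best$mapped_count,
        fit = best$fit,
        features = paste(names(best$assignment), collapse = ";"))
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(id = character(0), conformer = character(0),
                          mapped = integer(0), fit = numeric(0),
                          features = character(0))
  hits <- hits[order(-hits$fit, hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, counts = counts)
}
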