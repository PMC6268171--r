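# Zinc-binding-group detection: the selective feature chemistry of the
# zinc-binder pharmacophore feature. The class dictionary lives in
# inst/extdata/zbg_patterns.yaml (versioned data); this file interprets it.
# Allowed classes: carboxyl, phosphate, imidazole, 1,2,3-/1,2,4-triazole,
# tetrazole, thiadiazole, 1-hydroxy-2-oxo derivatives. Hydroxamates and
# thiols are never reported, even embedded in molecules that also carry an
# allowed class.

#' Load the zinc-binding-group pattern dictionary
#'
#' @param path optional path to an alternative pattern file.
#' @return parsed dictionary list (`version`, `allowed`, `excluded`).
#' @export
zbg_patterns <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "zbg_patterns.yaml", package = "zbscreen")
  yaml::read_yaml(path)
}

#' Detect zinc-binding groups
#'
#' Reports all non-overlapping occurrences of the eight allowed classes,
#' each with its matched atoms and the coordinating atoms presented to the
#' metal (always N or O). Atoms belonging to an excluded group (hydroxamate,
#' thiol) veto any allowed match they overlap, but never the rest of the
#' molecule.
#'
#' @param mol a `mol_record`.
#' @param patterns dictionary from [zbg_patterns()].
#' @return list of matches: `class`, `atoms` (indices), `coordinating`
#'   (indices); empty list when nothing matches.
#' @export
detect_zbg <- function(mol, patterns = zbg_patterns()) {
  validate_mol(mol)
  ctx <- list(adj = mol_adj(mol), h = implicit_h(mol),
              el = mol$atoms$element, ch = mol$atoms$charge,
              deg = heavy_degree(mol), rings = mol_rings(mol),
              arom = aromatic_rings(mol))
  excluded_atoms <- integer(0)
  for (nm in names(patterns$excluded)) {
    spec <- patterns$excluded[[nm]]
    for (m in run_zbg_matcher(mol, ctx, spec))
      excluded_atoms <- union(excluded_atoms, m$atoms)
  }
  out <- list()
  used <- integer(0)
  for (nm in names(patterns$allowed)) {
    spec <- patterns$allowed[[nm]]
    for (m in run_zbg_matcher(mol, ctx, spec)) {
      if (length(intersect(m$atoms, used))) next          # non-overlapping
      if (length(intersect(m$atoms, excluded_atoms))) next # exclusion veto
      used <- union(used, m$atoms)
      out[[length(out) + 1]] <- list(class = nm, atoms = sort(m$atoms),
                                     coordinating = sort(m$coordinating))
    }
  }
  out
}

run_zbg_matcher <- function(mol, ctx, spec) {
  switch(spec$matcher,
    carboxyl = zbg_carboxyl(mol, ctx),
    phosphate = zbg_phosphate(mol, ctx),
    ring = zbg_ring(mol, ctx, spec$sequences),
    hydroxy_oxo = zbg_hydroxy_oxo(mol, ctx),
    hydroxamate = zbg_hydroxamate(mol, ctx),
    thiol = zbg_thiol(mol, ctx),
    stop("unknown zbg matcher: ", spec$matcher))
}

# free hydroxyl or anionic oxygen (terminal)
is_free_oxygen <- function(ctx, i) {
  ctx$el[i] == "O" && ctx$deg[i] == 1 && (ctx$h[i] > 0 || ctx$ch[i] < 0)
}

zbg_carboxyl <- function(mol, ctx) {
  out <- list()
  for (c_at in which(ctx$el == "C")) {
    nb <- ctx$adj[[c_at]]
    o_dbl <- nb$nbr[nb$order == 2 & ctx$el[nb$nbr] == "O"]
    o_sgl <- nb$nbr[nb$order == 1 & ctx$el[nb$nbr] == "O"]
    o_sgl <- o_sgl[vapply(o_sgl, function(o) is_free_oxygen(ctx, o), logical(1))]
    if (length(o_dbl) && length(o_sgl))
      out[[length(out) + 1]] <- list(atoms = c(c_at, o_dbl[1], o_sgl[1]),
                                     coordinating = c(o_dbl[1], o_sgl[1]))
  }
  out
}

zbg_phosphate <- function(mol, ctx) {
  out <- list()
  for (p_at in which(ctx$el == "P")) {
    nb <- ctx$adj[[p_at]]
    o_all <- nb$nbr[ctx$el[nb$nbr] == "O"]
    o_dbl <- nb$nbr[nb$order == 2 & ctx$el[nb$nbr] == "O"]
    o_free <- o_all[vapply(o_all, function(o) is_free_oxygen(ctx, o), logical(1))]
    if (length(o_dbl) && length(o_free))
      out[[length(out) + 1]] <- list(atoms = c(p_at, o_all),
                                     coordinating = unique(c(o_dbl, o_free)))
  }
  out
}

# 5-membered conjugated ring matching a cyclic element sequence
# (rotation/reflection invariant => NH-tautomer invariant); coordinating
# atoms are ring nitrogens without hydrogen (pyridine-type lone pairs).
zbg_ring <- function(mol, ctx, sequences) {
  out <- list()
  b <- mol$bonds
  for (r in ctx$rings) {
    if (length(r) != 5) next
    dbl <- 0
    for (i in seq_along(r)) {
      j <- if (i == length(r)) 1 else i + 1
      hit <- which((b$a1 == r[i] & b$a2 == r[j]) | (b$a1 == r[j] & b$a2 == r[i]))
      if (length(hit) && b$order[hit[1]] == 2) dbl <- dbl + 1
    }
    is_arom <- any(vapply(ctx$arom, function(ar) setequal(ar, r), logical(1)))
    if (!is_arom && dbl < 2) next
    elseq <- ctx$el[r]
    matched <- FALSE
    for (s in sequences) {
      s <- unlist(s)
      for (rot in seq_along(r)) {
        fwd <- c(elseq[rot:length(elseq)], elseq[seq_len(rot - 1)])
        if (all(fwd == s) || all(rev(fwd) == s)) { matched <- TRUE; break }
      }
      if (matched) break
    }
    if (!matched) next
    coord <- r[ctx$el[r] == "N" & ctx$h[r] == 0]
    if (!length(coord)) coord <- r[ctx$el[r] == "N"]
    out[[length(out) + 1]] <- list(atoms = r, coordinating = coord)
  }
  out
}

# enol/phenol/olate O on a carbon 1,2-adjacent or peri (two bonds) to a
# carbonyl carbon; catechols (no carbonyl) never match.
zbg_hydroxy_oxo <- function(mol, ctx) {
  out <- list()
  carbonyl_c <- which(vapply(seq_len(n_atoms(mol)), function(i)
    ctx$el[i] == "C" && any(ctx$adj[[i]]$order == 2 &
                            ctx$el[ctx$adj[[i]]$nbr] == "O"), logical(1)))
  for (o_at in which(ctx$el == "O")) {
    if (!is_free_oxygen(ctx, o_at)) next
    a_c <- ctx$adj[[o_at]]$nbr[1]
    if (is.na(a_c) || ctx$el[a_c] != "C") next
    if (a_c %in% carbonyl_c) next    # that is a carboxyl, not an enol
    nb1 <- ctx$adj[[a_c]]$nbr
    cands <- list()
    for (b_c in intersect(nb1, carbonyl_c)) cands[[length(cands) + 1]] <- b_c
    for (mid in nb1) for (b_c in intersect(ctx$adj[[mid]]$nbr, carbonyl_c))
      if (b_c != a_c) cands[[length(cands) + 1]] <- b_c
    for (b_c in unique(unlist(cands))) {
      nbB <- ctx$adj[[b_c]]
      o_keto <- nbB$nbr[nbB$order == 2 & ctx$el[nbB$nbr] == "O"][1]
      out[[length(out) + 1]] <- list(atoms = unique(c(o_at, a_c, b_c, o_keto)),
                                     coordinating = c(o_at, o_keto))
      break
    }
  }
  out
}

zbg_hydroxamate <- function(mol, ctx) {
  out <- list()
  for (n_at in which(ctx$el == "N")) {
    nb <- ctx$adj[[n_at]]
    o_hyd <- nb$nbr[ctx$el[nb$nbr] == "O" & nb$order == 1]
    o_hyd <- o_hyd[vapply(o_hyd, function(o)
      ctx$h[o] > 0 || ctx$ch[o] < 0, logical(1))]
    if (!length(o_hyd)) next
    c_carb <- nb$nbr[ctx$el[nb$nbr] == "C"]
    c_carb <- c_carb[vapply(c_carb, function(cc)
      any(ctx$adj[[cc]]$order == 2 & ctx$el[ctx$adj[[cc]]$nbr] == "O"),
      logical(1))]
    if (!length(c_carb)) next
    o_keto <- ctx$adj[[c_carb[1]]]$nbr[
      ctx$adj[[c_carb[1]]]$order == 2 &
      ctx$el[ctx$adj[[c_carb[1]]]$nbr] == "O"][1]
    out[[length(out) + 1]] <- list(
      atoms = c(n_at, o_hyd[1], c_carb[1], o_keto), coordinating = integer(0))
  }
  out
}

zbg_thiol <- function(mol, ctx) {
  out <- list()
  for (s_at in which(ctx$el == "S"))
    if (ctx$h[s_at] > 0 && ctx$deg[s_at] <= 1)
      out[[length(out) + 1]] <- list(atoms = s_at, coordinating = integer(0))
  out
}

#' Bidentate chelation geometry check
#'
#' True when two coordinating oxygens are separated by a distance inside the
#' window `center +/- half_width` (both bounds inclusive) — the ketone/
#' hydroxyl separation required for flavonoid-style zinc chelation.
#'
#' @param o1,o2 numeric xyz vectors (Angstrom).
#' @param center window centre (default 2.5 A).
#' @param half_width window half-width (default 0.5 A).
#' @return logical.
#' @export
chelation_geometry_ok <- function(o1, o2, center = 2.5, half_width = 0.5) {
  d <- vnorm(as.numeric(o1) - as.numeric(o2))
  d >= center - half_width && d <= center + half_width
}
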