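# Ligand preparation: ionization at physiological pH, tautomer and
# stereoisomer enumeration, and canonical deduplication. This is the only
# funnel stage permitted to increase the record count. pKa handling is a
# versioned rule table (inst/extdata/pka_rules.yaml), not a predictor; the
# tautomer rule set is a small curated transform list (lactam-lactim, azole
# NH shift, 1,3-keto-enol on dicarbonyls) chosen because azole and enol
# tautomers directly affect zinc-binding-group perception.

#' Load the ionization rule table
#' @param path optional alternative rule file.
#' @return parsed rule list.
#' @export
pka_rules <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pka_rules.yaml", package = "zbscreen")
  yaml::read_yaml(path)
}

#' Enumerate ionization states, tautomers and stereoisomers
#'
#' Returns the input form plus: ionized forms for every recognized group
#' whose pKa makes both protonation states populated in the pH window
#' (`[ph_low - 2, ph_high + 2]`), dominant forms for strongly shifted
#' groups, curated tautomers, and enumerated unassigned stereocentres
#' (up to 2^4 centres). Output is capped at `max_forms` with deterministic
#' priority ionization > tautomer > stereo; every form carries its parent id
#' in `$source` as `parent:<id>`.
#'
#' @param mol a `mol_record`.
#' @param ph_low,ph_high pH window (defaults 6.5-8.5).
#' @param max_forms cap on emitted forms (default 32).
#' @param rules ionization rule table from [pka_rules()].
#' @return list of `mol_record` (first element is the input form).
#' @export
enumerate_forms <- function(mol, ph_low = 6.5, ph_high = 8.5,
                            max_forms = 32L, rules = pka_rules()) {
  validate_mol(mol)
  lo <- ph_low - 2; hi <- ph_high + 2
  forms <- list(mol)
  # --- ionization -------------------------------------------------------
  sites <- find_ionizable_sites(mol, rules)
  for (s in sites) {
    toggled <- NULL
    if (s$kind == "acid" && s$pka <= hi) toggled <- deprotonate_at(mol, s$atom)
    if (s$kind == "base" && s$pka >= lo) toggled <- protonate_at(mol, s$atom)
    if (!is.null(toggled)) forms[[length(forms) + 1]] <- toggled
  }
  # --- tautomers (of the input form) ------------------------------------
  for (t in enumerate_tautomers(mol)) forms[[length(forms) + 1]] <- t
  # --- stereoisomers ----------------------------------------------------
  centres <- find_stereocentres(mol)
  if (length(centres)) {
    centres <- centres[seq_len(min(4L, length(centres)))]
    combos <- expand.grid(rep(list(c("R", "S")), length(centres)),
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(combos))) {
      v <- mol
      v$stereo <- data.frame(atom = centres,
                             config = as.character(combos[i, ]))
      forms[[length(forms) + 1]] <- v
    }
  }
  if (length(forms) > max_forms) {
    message("enumerate_forms('", mol$id, "'): ", length(forms),
            " forms truncated to ", max_forms)
    forms <- forms[seq_len(max_forms)]
  }
  for (i in seq_along(forms)) {
    forms[[i]]$source <- paste0("parent:", mol$id)
    if (i > 1) forms[[i]]$id <- paste0(mol$id, "_f", i - 1)
    validate_mol(forms[[i]])
  }
  forms
}

find_ionizable_sites <- function(mol, rules) {
  ctx <- list(adj = mol_adj(mol), h = implicit_h(mol),
              el = mol$atoms$element, ch = mol$atoms$charge,
              deg = heavy_degree(mol), rings = mol_rings(mol),
              arom = aromatic_rings(mol))
  sites <- list()
  add <- function(atom, grp)
    sites[[length(sites) + 1]] <<- list(atom = atom, group = grp$recognizer,
                                        pka = grp$pka, kind = grp$kind)
  for (nm in names(rules$groups)) {
    grp <- rules$groups[[nm]]
    hits <- switch(grp$recognizer,
      carboxylic_acid = {
        m <- zbg_carboxyl(mol, ctx)
        vapply(m, function(x) {
          o <- x$coordinating[vapply(x$coordinating, function(o)
            ctx$h[o] > 0, logical(1))]
          if (length(o)) o[1] else NA_integer_ }, integer(1))
      },
      phosphate_oh = {
        m <- zbg_phosphate(mol, ctx)
        vapply(m, function(x) {
          o <- x$coordinating[vapply(x$coordinating, function(o)
            ctx$h[o] > 0, logical(1))]
          if (length(o)) o[1] else NA_integer_ }, integer(1))
      },
      tetrazole_nh = {
        m <- zbg_ring(mol, ctx, list(c("N", "N", "N", "N", "C")))
        vapply(m, function(x) {
          nh <- x$atoms[ctx$el[x$atoms] == "N" & ctx$h[x$atoms] > 0]
          if (length(nh)) nh[1] else NA_integer_ }, integer(1))
      },
      phenol = {
        aromset <- unique(unlist(ctx$arom))
        which(vapply(seq_len(n_atoms(mol)), function(i)
          ctx$el[i] == "O" && ctx$deg[i] == 1 && ctx$h[i] > 0 &&
          ctx$adj[[i]]$nbr[1] %in% aromset &&
          !fc_acidic_oxygen(mol)[i], logical(1)))
      },
      sulfonic_acid = {
        which(vapply(seq_len(n_atoms(mol)), function(i) {
          if (ctx$el[i] != "O" || ctx$deg[i] != 1 || ctx$h[i] == 0) return(FALSE)
          s <- ctx$adj[[i]]$nbr[1]
          ctx$el[s] == "S" &&
            sum(ctx$adj[[s]]$order == 2 & ctx$el[ctx$adj[[s]]$nbr] == "O") >= 2
        }, logical(1)))
      },
      aliphatic_amine = {
        aromset <- unique(unlist(ctx$arom))
        which(vapply(seq_len(n_atoms(mol)), function(i) {
          if (ctx$el[i] != "N" || ctx$ch[i] != 0) return(FALSE)
          if (i %in% aromset) return(FALSE)
          nb <- ctx$adj[[i]]
          if (length(nb$nbr) == 0 || any(nb$order > 1)) return(FALSE)
          # not an amide/aniline nitrogen
          all(vapply(nb$nbr, function(j)
            ctx$el[j] == "C" && !(j %in% aromset) &&
            !any(ctx$adj[[j]]$order == 2 & ctx$el[ctx$adj[[j]]$nbr] == "O"),
            logical(1)))
        }, logical(1)))
      },
      imidazole_base = {
        m <- zbg_ring(mol, ctx, list(c("N", "C", "N", "C", "C")))
        vapply(m, function(x) {
          np <- x$atoms[ctx$el[x$atoms] == "N" & ctx$h[x$atoms] == 0]
          if (length(np)) np[1] else NA_integer_ }, integer(1))
      },
      integer(0))
    for (a in hits) if (!is.na(a) && length(a)) add(a, grp)
  }
  sites
}

deprotonate_at <- function(mol, atom) {
  if (implicit_h(mol)[atom] < 1) return(NULL)
  m <- mol
  m$atoms$charge[atom] <- m$atoms$charge[atom] - 1L
  m
}

protonate_at <- function(mol, atom) {
  m <- mol
  m$atoms$charge[atom] <- m$atoms$charge[atom] + 1L
  m
}

# Curated tautomer transforms. Each returns modified copies or nothing.
enumerate_tautomers <- function(mol) {
  out <- list()
  adj <- mol_adj(mol)
  el <- mol$atoms$element
  h <- implicit_h(mol)
  b <- mol$bonds
  find_bond <- function(a1, a2)
    which((b$a1 == a1 & b$a2 == a2) | (b$a1 == a2 & b$a2 == a1))[1]
  # lactim -> lactam: N=C-OH  =>  NH-C=O
  for (c_at in which(el == "C")) {
    nb <- adj[[c_at]]
    n_dbl <- nb$nbr[nb$order == 2 & el[nb$nbr] == "N"]
    o_h <- nb$nbr[nb$order == 1 & el[nb$nbr] == "O"]
    o_h <- o_h[h[o_h] > 0 & heavy_degree(mol)[o_h] == 1]
    if (length(n_dbl) && length(o_h)) {
      m <- mol
      m$bonds$order[find_bond(c_at, n_dbl[1])] <- 1L
      m$bonds$order[find_bond(c_at, o_h[1])] <- 2L
      out[[length(out) + 1]] <- m
    }
  }
  # lactam -> lactim: NH-C=O  =>  N=C-OH
  for (c_at in which(el == "C")) {
    nb <- adj[[c_at]]
    o_dbl <- nb$nbr[nb$order == 2 & el[nb$nbr] == "O"]
    n_h <- nb$nbr[nb$order == 1 & el[nb$nbr] == "N"]
    n_h <- n_h[h[n_h] > 0]
    if (length(o_dbl) && length(n_h)) {
      m <- mol
      m$bonds$order[find_bond(c_at, o_dbl[1])] <- 1L
      m$bonds$order[find_bond(c_at, n_h[1])] <- 2L
      out[[length(out) + 1]] <- m
    }
  }
  # azole NH shift: re-kekulize a 5-ring with >= 2 nitrogens so each ring N
  # takes a turn carrying the hydrogen
  ctx_rings <- mol_rings(mol)
  for (r in ctx_rings) {
    if (length(r) != 5 || sum(el[r] == "N") < 2) next
    ring_b <- vapply(seq_along(r), function(i) {
      j <- if (i == 5) 1 else i + 1; find_bond(r[i], r[j]) }, integer(1))
    if (anyNA(ring_b) || sum(b$order[ring_b] == 2) < 2) next
    exo_ok <- all(vapply(r, function(a) {
      nb <- adj[[a]]; !any(nb$order >= 2 & !(nb$nbr %in% r)) }, logical(1)))
    if (!exo_ok) next
    cur_nh <- r[el[r] == "N" & h[r] > 0]
    for (target in r[el[r] == "N"]) {
      if (length(cur_nh) && target == cur_nh[1]) next
      i0 <- which(r == target)
      ord <- c(r[i0:5], r[seq_len(i0 - 1)])
      m <- mol
      pat <- c(1L, 2L, 1L, 2L, 1L)   # single bonds flank the NH position
      okv <- TRUE
      for (i in seq_len(5)) {
        j <- if (i == 5) 1 else i + 1
        bi <- find_bond(ord[i], ord[j])
        m$bonds$order[bi] <- pat[i]
      }
      okv <- tryCatch({ validate_mol(m); all(implicit_h(m)[r[el[r] == "N"]] ==
        as.integer(r[el[r] == "N"] == target)) }, error = function(e) FALSE)
      if (okv) out[[length(out) + 1]] <- m
    }
  }
  # 1,3-keto-enol on dicarbonyls: O=C-CH-C=O => O=C-C=C-OH
  for (mid in which(el == "C")) {
    if (h[mid] < 1) next
    nb <- adj[[mid]]
    flank <- nb$nbr[nb$order == 1 & el[nb$nbr] == "C"]
    carb <- flank[vapply(flank, function(cc)
      any(adj[[cc]]$order == 2 & el[adj[[cc]]$nbr] == "O"), logical(1))]
    if (length(carb) >= 2) {
      cc <- carb[1]
      o_at <- adj[[cc]]$nbr[adj[[cc]]$order == 2 & el[adj[[cc]]$nbr] == "O"][1]
      m <- mol
      m$bonds$order[find_bond(mid, cc)] <- 2L
      m$bonds$order[find_bond(cc, o_at)] <- 1L
      out[[length(out) + 1]] <- m
    }
  }
  # drop duplicates / identity
  keys <- vapply(out, function(m) tryCatch(canonical_key(m),
                                           error = function(e) NA_character_),
                 character(1))
  ok <- !is.na(keys) & !duplicated(keys) & keys != canonical_key(mol)
  out[ok]
}

# Potential (unassigned) stereocentres: sp3 carbons with four distinct
# substituent environments, hydrogen counted as one substituent.
find_stereocentres <- function(mol) {
  if (!is.null(mol$stereo) && nrow(mol$stereo)) return(integer(0))
  adj <- mol_adj(mol)
  el <- mol$atoms$element
  h <- implicit_h(mol)
  # environment code per atom: 2 rounds of neighborhood hashing
  codes <- vapply(seq_len(n_atoms(mol)), function(i)
    zb_hash(sprintf("%s|%d", el[i], mol$atoms$charge[i])), numeric(1))
  for (r in 1:3) {
    codes <- vapply(seq_len(n_atoms(mol)), function(i) {
      nb <- adj[[i]]
      zb_hash(paste(codes[i],
                    paste(sort(sprintf("%d:%.0f", nb$order, codes[nb$nbr])),
                          collapse = ","), sep = "|"))
    }, numeric(1))
  }
  out <- integer(0)
  for (i in which(el == "C")) {
    nb <- adj[[i]]
    if (any(nb$order > 1)) next
    nsub <- length(nb$nbr) + (h[i] > 0)
    if (nsub != 4 || h[i] > 1) next
    branch <- codes[nb$nbr]
    if (h[i] == 1) branch <- c(branch, -1)
    if (!anyDuplicated(branch)) out <- c(out, i)
  }
  out
}

#' Deduplicate a record collection by canonical structure
#'
#' Unique by canonical structure key (canonical SMILES including charges plus
#' assigned stereo labels); stable keep-first, order-preserving, idempotent.
#'
#' @param records list of `mol_record`.
#' @return deduplicated list.
#' @export
deduplicate <- function(records) {
  if (!length(records)) return(records)
  keys <- canonical_keys(records)
  records[!duplicated(keys)]
}
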