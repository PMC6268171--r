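# Sparse extended-connectivity fingerprints and the three similarity
# measures printed with the screening protocol:
#
#   Tanimoto  SA / (SA + SB + SC)
#   Dice      2*SA / (2*SA + SB + SC)
#   Cosine    SA / sqrt((SA + SB) * (SA + SC))
#
# where SA = features present in both target and reference, SB = features in
# the target only, SC = features in the reference only.
#
# Two atom abstractions are provided. The functional-class scheme seeds each
# atom with pharmacophoric flags (donor, acceptor, positively/negatively
# ionizable, aromatic, halogen) and by default removes duplicate features
# (bit semantics). The atom-type scheme seeds with element, charge,
# hybridization proxy and degree, and by default keeps duplicate counts
# (count semantics). Environments are grown iteratively to a maximum
# topological diameter (default 6, i.e. three growth rounds) and hashed with
# the package's fixed 31-bit hash; hash collisions are tolerated.

# Numeric feature-id arithmetic: 31-bit Horner mixing with the MINSTD
# multiplier. Products stay below 2^47, exact in doubles.
FP_P <- 2147483647
fp_mix <- function(h, v) (h * 48271 + v) %% FP_P

fp_seed_codes <- function(mol, scheme) {
  n <- n_atoms(mol)
  if (n == 0) return(numeric(0))
  el <- mol$atoms$element; ch <- mol$atoms$charge
  deg <- heavy_degree(mol)
  h <- implicit_h(mol)
  arom <- seq_len(n) %in% aromatic_atoms(mol)
  adj <- mol_adj(mol)
  maxord <- vapply(seq_len(n), function(i)
    if (length(adj[[i]]$nbr)) max(adj[[i]]$order) else 0L, numeric(1))
  if (scheme == "atom-type") {
    ei <- match(el, names(ATOMIC_MASS), nomatch = 50L)
    hyb <- ifelse(arom | maxord == 2, 2L, ifelse(maxord >= 3, 1L, 3L))
    raw <- (((ei * 31 + ch + 8) * 31 + hyb) * 31 + deg) * 31 + h
  } else {
    donor <- el %in% c("N", "O") & h > 0
    acceptor <- el %in% c("N", "O") & ch <= 0
    posion <- (el == "N" & ch > 0) | (el == "N" & h > 0 & !arom & maxord == 1)
    negion <- ch < 0 | fc_acidic_oxygen(mol)
    halogen <- el %in% HALOGENS
    raw <- donor + 2 * acceptor + 4 * posion + 8 * negion + 16 * arom +
      32 * halogen + 64   # offset so an all-zero flag atom still mixes
  }
  fp_mix(raw, 1)
}

# acidic hydroxyl oxygens (carboxylic/sulfonic/phosphoric O-H) for the
# negatively-ionizable functional-class flag
fc_acidic_oxygen <- function(mol) {
  n <- n_atoms(mol)
  out <- logical(n)
  if (n == 0) return(out)
  adj <- mol_adj(mol)
  h <- implicit_h(mol)
  for (i in seq_len(n)) {
    if (mol$atoms$element[i] != "O" || h[i] == 0) next
    for (j in adj[[i]]$nbr) {
      if (mol$atoms$element[j] %in% c("C", "S", "P") &&
          any(adj[[j]]$order == 2 &
              mol$atoms$element[adj[[j]]$nbr] == "O")) { out[i] <- TRUE; break }
    }
  }
  out
}

#' Sparse circular fingerprint
#'
#' @param mol a `mol_record`.
#' @param scheme `"functional-class"` or `"atom-type"`.
#' @param max_distance maximum topological diameter of grown environments
#'   (default 6).
#' @param mode `"bit"` or `"count"`; default `"bit"` for functional-class and
#'   `"count"` for atom-type (duplicates removed vs. duplicates returned).
#' @return a `sparse_fp`: feature-id -> count map plus scheme metadata.
#' @export
fingerprint <- function(mol, scheme = c("functional-class", "atom-type"),
                        max_distance = 6L, mode = NULL) {
  scheme <- match.arg(scheme)
  if (is.null(mode)) mode <- if (scheme == "atom-type") "count" else "bit"
  mode <- match.arg(mode, c("bit", "count"))
  n <- n_atoms(mol)
  if (n == 0) {
    warning("empty molecule '", mol$id, "': empty fingerprint", call. = FALSE)
    return(structure(list(entries = numeric(0), scheme = scheme,
                          max_distance = as.integer(max_distance), mode = mode),
                     class = "sparse_fp"))
  }
  adj <- mol_adj(mol)
  nbrs <- lapply(adj, `[[`, "nbr")
  ords <- lapply(adj, `[[`, "order")
  codes <- fp_seed_codes(mol, scheme)
  feats <- codes
  n_iter <- max_distance %/% 2L
  for (r in seq_len(n_iter)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      v <- sort((codes[nbrs[[i]]] * 8 + ords[[i]]) %% FP_P)
      hh <- fp_mix(r, codes[i])
      for (x in v) hh <- fp_mix(hh, x)
      nxt[i] <- hh
    }
    codes <- nxt
    feats <- c(feats, codes)
  }
  tab <- table(feats)
  entries <- as.numeric(tab)
  names(entries) <- names(tab)
  if (mode == "bit") entries[] <- 1
  structure(list(entries = entries, scheme = scheme,
                 max_distance = as.integer(max_distance), mode = mode),
            class = "sparse_fp")
}

#' @export
print.sparse_fp <- function(x, ...) {
  cat(sprintf("<sparse_fp %s/%d, %s mode: %d features>\n", x$scheme,
              x$max_distance, x$mode, length(x$entries)))
  invisible(x)
}

#' Similarity components SA / SB / SC
#'
#' Bit mode uses set semantics (counts ignored); count mode uses
#' SA = sum(min), SB = sum(target - min), SC = sum(reference - min).
#'
#' @param target,reference `sparse_fp` objects with identical scheme and
#'   max_distance.
#' @param mode `"bit"` or `"count"`; defaults to the fingerprints' own mode.
#' @return list with `SA`, `SB`, `SC`, `mode`.
#' @export
fp_components <- function(target, reference, mode = NULL) {
  if (target$scheme != reference$scheme ||
      target$max_distance != reference$max_distance)
    stop("fingerprint scheme mismatch: ", target$scheme, "/",
         target$max_distance, " vs ", reference$scheme, "/",
         reference$max_distance)
  if (is.null(mode)) mode <- target$mode
  mode <- match.arg(mode, c("bit", "count"))
  t_e <- target$entries; r_e <- reference$entries
  if (mode == "bit") { t_e[] <- pmin(t_e, 1); r_e[] <- pmin(r_e, 1) }
  common <- intersect(names(t_e), names(r_e))
  sa <- sum(pmin(t_e[common], r_e[common]))
  sb <- sum(t_e) - sa
  sc <- sum(r_e) - sa
  list(SA = sa, SB = sb, SC = sc, mode = mode)
}

#' Similarity from components
#'
#' Evaluates the selected measure exactly as printed: Tanimoto
#' SA/(SA+SB+SC), Dice 2SA/(2SA+SB+SC), Cosine SA/sqrt((SA+SB)(SA+SC)).
#' Empty-vs-empty comparisons return 0 with a warning (documented
#' convention avoiding 0/0).
#'
#' @param comp output of [fp_components()].
#' @param measure `"tanimoto"`, `"dice"` or `"cosine"`.
#' @return similarity in `[0, 1]`.
#' @export
fp_similarity <- function(comp, measure = c("tanimoto", "dice", "cosine")) {
  measure <- match.arg(measure)
  sa <- comp$SA; sb <- comp$SB; sc <- comp$SC
  if (any(c(sa, sb, sc) < 0)) stop("negative similarity components")
  if (sa == 0 && sb == 0 && sc == 0) {
    warning("empty-vs-empty fingerprint comparison: similarity 0 by convention",
            call. = FALSE)
    return(0)
  }
  if (sa == 0) return(0)
  switch(measure,
    tanimoto = sa / (sa + sb + sc),
    dice = 2 * sa / (2 * sa + sb + sc),
    cosine = sa / sqrt((sa + sb) * (sa + sc)))
}

#' Top-k similarity search against a database
#'
#' Scores every database molecule against the reference and returns the `k`
#' most similar, sorted by similarity descending with ties broken stably by
#' database input order. Equivalent to an exhaustive scan by construction.
#'
#' @param reference a `mol_record` (or precomputed `sparse_fp`).
#' @param db list of `mol_record`, or a precomputed list of `sparse_fp` with
#'   ids as names.
#' @param k number of hits (default 500).
#' @param measure similarity measure.
#' @param scheme fingerprint scheme.
#' @param max_distance fingerprint diameter.
#' @param run_id provenance tag for the run.
#' @return data.frame (`hit_list`): reference_id, target_id, measure, scheme,
#'   similarity, rank, run_id.
#' @export
top_k_similar <- function(reference, db, k = 500L,
                          measure = c("tanimoto", "dice", "cosine"),
                          scheme = c("functional-class", "atom-type"),
                          max_distance = 6L, run_id = "run1") {
  measure <- match.arg(measure); scheme <- match.arg(scheme)
  if (k < 1) stop("k must be >= 1")
  ref_id <- if (inherits(reference, "mol_record")) reference$id else "reference"
  ref_fp <- if (inherits(reference, "sparse_fp")) reference
            else fingerprint(reference, scheme, max_distance)
  if (!length(db)) {
    warning("empty database: empty hit list", call. = FALSE)
    return(empty_hitlist())
  }
  db_fps <- if (inherits(db[[1]], "sparse_fp")) db
            else { fps <- lapply(db, fingerprint, scheme = scheme,
                                 max_distance = max_distance)
                   names(fps) <- vapply(db, function(m) m$id, character(1)); fps }
  sims <- vapply(db_fps, function(fp)
    fp_similarity(fp_components(fp, ref_fp), measure), numeric(1))
  ord <- order(-sims, seq_along(sims))   # stable: ties keep input order
  top <- ord[seq_len(min(k, length(ord)))]
  data.frame(reference_id = ref_id, target_id = names(db_fps)[top],
             measure = measure, scheme = scheme,
             similarity = unname(sims[top]), rank = seq_along(top),
             run_id = run_id)
}

empty_hitlist <- function() {
  data.frame(reference_id = character(0), target_id = character(0),
             measure = character(0), scheme = character(0),
             similarity = numeric(0), rank = integer(0), run_id = character(0))
}

#' Multi-run similarity battery
#'
#' One top-k run per (reference x measure x scheme). The merged,
#' pre-deduplication row count is
#' `n_references * n_measures * n_schemes * min(k, db size)`; with five
#' references, the three measures, both schemes and k = 500 against a
#' database of at least 500 molecules this yields 15,000 rows.
#'
#' @param references list of `mol_record`.
#' @param db list of `mol_record`.
#' @param k hits per run (default 500).
#' @param measures character vector of measures.
#' @param schemes character vector of schemes.
#' @param max_distance fingerprint diameter.
#' @return merged hit-list data.frame with run provenance.
#' @export
run_similarity_battery <- function(references, db, k = 500L,
                                   measures = c("tanimoto", "dice", "cosine"),
                                   schemes = c("functional-class", "atom-type"),
                                   max_distance = 6L) {
  if (!length(references) || !length(measures) || !length(schemes))
    stop("references, measures and schemes must be non-empty")
  out <- list()
  for (scheme in schemes) {
    db_fps <- lapply(db, fingerprint, scheme = scheme,
                     max_distance = max_distance)
    names(db_fps) <- vapply(db, function(m) m$id, character(1))
    for (ref in references) {
      ref_fp <- fingerprint(ref, scheme, max_distance)
      for (measure in measures) {
        run_id <- sprintf("%s|%s|%s|k=%d", ref$id, measure, scheme, k)
        hl <- top_k_similar(ref_fp, db_fps, k, measure, scheme,
                            max_distance, run_id)
        if (nrow(hl)) hl$reference_id <- ref$id
        out[[length(out) + 1]] <- hl
      }
    }
  }
  do.call(rbind, out)
}
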