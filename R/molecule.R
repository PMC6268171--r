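# Molecule records: a light molecular-graph container used by every stage.
# Heavy atoms only; hydrogens are implicit and derived from a standard
# valence model. Parsing and canonicalization are delegated to Open Babel
# through ChemmineR/ChemmineOB; this file owns the graph-level perception
# (implicit H, rings, aromaticity) that the fingerprint, filter, ZBG and
# pharmacophore layers consume.

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Se = 78.971,
  Br = 79.904, I = 126.904, Zn = 65.38, Na = 22.990, K = 39.098
)

HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a molecule record
#'
#' A `mol_record` is the package's unit of exchange: an identified heavy-atom
#' molecular graph with optional 3D coordinates. Hydrogens are implicit and
#' recomputed on demand from a fixed valence model, so edits such as
#' deprotonation are expressed purely through formal charges and bond orders.
#'
#' @param id unique identifier string.
#' @param atoms data.frame with columns `element` (symbol) and `charge`
#'   (integer formal charge).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (1, 2 or 3).
#' @param coords optional numeric matrix (n_atoms x 3) of 3D coordinates in
#'   Angstrom.
#' @param source provenance tag.
#' @param stereo optional data.frame of assigned stereocentres
#'   (columns `atom`, `config`), carried through enumeration and dedup.
#' @return an object of class `mol_record`.
#' @export
mol_record <- function(id, atoms, bonds, coords = NULL, source = "r",
                       stereo = NULL) {
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge %||% 0L))
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                        order = as.integer(bonds$order))
  }
  n <- nrow(atoms)
  if (nrow(bonds) && (any(bonds$a1 < 1) || any(bonds$a2 < 1) ||
                      any(bonds$a1 > n) || any(bonds$a2 > n)))
    stop("bond atom indices out of range for molecule '", id, "'")
  if (!is.null(coords)) {
    coords <- matrix(as.numeric(coords), ncol = 3)
    if (nrow(coords) != n)
      stop("coords3d length must equal atom count for molecule '", id, "'")
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 coords = coords, source = source, stereo = stereo),
            class = "mol_record")
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record %s: %d atoms, %d bonds%s>\n", x$id,
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$coords)) ", 3D" else ""))
  invisible(x)
}

#' Number of heavy atoms in a record
#' @param mol a `mol_record`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

# adjacency list: per atom a list(nbr = integer vector, order = integer
# vector) of bonded neighbours and bond orders
mol_adj <- function(mol) {
  n <- n_atoms(mol)
  b <- mol$bonds
  adj <- rep(list(list(nbr = integer(0), order = integer(0))), n)
  if (nrow(b)) {
    ends <- c(b$a1, b$a2); other <- c(b$a2, b$a1); ord <- c(b$order, b$order)
    sp <- split(seq_along(ends), factor(ends, levels = seq_len(n)))
    for (i in seq_len(n)) {
      ix <- sp[[i]]
      if (length(ix)) adj[[i]] <- list(nbr = other[ix], order = ord[ix])
    }
  }
  adj
}

bond_order_sum <- function(mol) {
  n <- n_atoms(mol)
  s <- numeric(n)
  b <- mol$bonds
  if (nrow(b)) for (i in seq_len(nrow(b))) {
    s[b$a1[i]] <- s[b$a1[i]] + b$order[i]
    s[b$a2[i]] <- s[b$a2[i]] + b$order[i]
  }
  s
}

heavy_degree <- function(mol) {
  n <- n_atoms(mol)
  d <- integer(n)
  b <- mol$bonds
  if (nrow(b)) for (i in seq_len(nrow(b))) {
    d[b$a1[i]] <- d[b$a1[i]] + 1L
    d[b$a2[i]] <- d[b$a2[i]] + 1L
  }
  d
}

# Implicit hydrogen counts under a fixed valence model.
# Effective valences: C 4 (less |charge|), N 3 + charge, O 2 + charge,
# S smallest of 2/4/6 covering the bond sum, P 3 or 5, halogens/H 1, B 3.
implicit_h <- function(mol) {
  bos <- bond_order_sum(mol)
  el <- mol$atoms$element
  ch <- mol$atoms$charge
  n <- n_atoms(mol)
  h <- numeric(n)
  for (i in seq_len(n)) {
    v <- switch(el[i],
      C = 4 - abs(ch[i]),
      N = 3 + ch[i],
      O = 2 + ch[i],
      S = { base <- c(2, 4, 6); v0 <- base[base >= bos[i] - ch[i]]
            (if (length(v0)) v0[1] else 6) + ch[i] },
      P = if (bos[i] > 3) 5 else 3,
      B = 3,
      Si = 4,
      Se = 2,
      `F` = 1, Cl = 1, Br = 1, I = 1, H = 1,
      0)
    h[i] <- max(0, v - bos[i])
  }
  h
}

#' Validate a molecule against the package valence model
#' @param mol a `mol_record`.
#' @return TRUE invisibly; errors naming the record on valence violations.
#' @export
validate_mol <- function(mol) {
  bos <- bond_order_sum(mol)
  el <- mol$atoms$element
  maxv <- vapply(seq_len(n_atoms(mol)), function(i) switch(el[i],
    C = 4, N = 4, O = 3, S = 6, P = 5, B = 3, Si = 4, Se = 6,
    `F` = 1, Cl = 1, Br = 1, I = 1, H = 1, 8), numeric(1))
  bad <- which(bos - mol$atoms$charge > maxv)
  if (length(bad))
    stop("unsanitizable molecule '", mol$id, "': valence exceeded at atom(s) ",
         paste(bad, collapse = ","))
  invisible(TRUE)
}

# Smallest rings: for every bond that lies in a cycle, the shortest cycle
# through it (BFS with the bond removed). Returns a list of unique atom-index
# vectors ordered around the ring.
mol_rings <- function(mol, max_size = 8) {
  b <- mol$bonds
  if (!nrow(b)) return(list())
  adj <- mol_adj(mol)
  rings <- list()
  seen <- character(0)
  for (k in seq_len(nrow(b))) {
    u <- b$a1[k]; v <- b$a2[k]
    # BFS from u to v avoiding the direct edge
    n <- n_atoms(mol)
    prev <- rep(NA_integer_, n); distv <- rep(NA_integer_, n)
    distv[u] <- 0L
    q <- u
    while (length(q)) {
      cur <- q[1]; q <- q[-1]
      if (cur == v) break
      for (w in adj[[cur]]$nbr) {
        if (cur == u && w == v) next
        if (is.na(distv[w])) {
          distv[w] <- distv[cur] + 1L; prev[w] <- cur; q <- c(q, w)
        }
      }
    }
    if (is.na(distv[v]) || distv[v] + 1L > max_size) next
    path <- v
    while (path[length(path)] != u) path <- c(path, prev[path[length(path)]])
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1]] <- path }
  }
  rings
}

# Aromaticity: Hueckel-style perception on 5/6-membered smallest rings of a
# kekulized graph. Each ring atom contributes 1 pi electron if it carries a
# double bond inside the ring, 2 if it is a heteroatom (or anion) donating a
# lone pair, and disqualifies the ring if saturated. A ring is aromatic when
# every atom contributes and the count is 6.
aromatic_rings <- function(mol) {
  rings <- mol_rings(mol)
  rings <- rings[vapply(rings, length, 1L) %in% c(5L, 6L)]
  if (!length(rings)) return(list())
  b <- mol$bonds
  dbl_partner <- rep(list(integer(0)), n_atoms(mol))
  if (nrow(b)) for (i in seq_len(nrow(b))) if (b$order[i] == 2L) {
    dbl_partner[[b$a1[i]]] <- c(dbl_partner[[b$a1[i]]], b$a2[i])
    dbl_partner[[b$a2[i]]] <- c(dbl_partner[[b$a2[i]]], b$a1[i])
  }
  el <- mol$atoms$element; ch <- mol$atoms$charge
  keep <- list()
  for (r in rings) {
    pi <- 0; ok <- TRUE
    for (a in r) {
      in_ring_dbl <- any(dbl_partner[[a]] %in% r)
      exo_dbl <- length(dbl_partner[[a]]) > 0 && !in_ring_dbl
      if (in_ring_dbl) pi <- pi + 1
      else if (el[a] %in% c("N", "O", "S", "Se") || ch[a] < 0) pi <- pi + 2
      else if (exo_dbl) pi <- pi + 0   # exocyclic C=O: sp2 but contributes none
      else { ok <- FALSE; break }
    }
    if (ok && pi == 6) keep[[length(keep) + 1]] <- r
  }
  keep
}

aromatic_atoms <- function(mol) {
  unique(unlist(aromatic_rings(mol))) %||% integer(0)
}

ring_atoms <- function(mol) unique(unlist(mol_rings(mol))) %||% integer(0)

# ---- conversion to / from ChemmineR SDF objects -------------------------

MDL_CHARGE_CODE <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L, `-3` = 7L)

mol_to_sdf <- function(mol) {
  n <- n_atoms(mol)
  cn <- c("C1","C2","C3","C5","C6","C7","C8","C9","C10","C11","C12","C13",
          "C14","C15","C16")
  ab <- matrix(0, n, length(cn),
               dimnames = list(paste(mol$atoms$element, seq_len(n), sep = "_"), cn))
  if (!is.null(mol$coords)) ab[, 1:3] <- mol$coords
  code <- MDL_CHARGE_CODE[as.character(mol$atoms$charge)]
  code[is.na(code)] <- 0L
  ab[, "C6"] <- code
  nb <- nrow(mol$bonds)
  bb <- matrix(0L, nb, 3, dimnames = list(seq_len(nb)[0:nb], c("C1","C2","C3")))
  if (nb) { bb[, 1] <- mol$bonds$a1; bb[, 2] <- mol$bonds$a2; bb[, 3] <- mol$bonds$order }
  header <- c(Molecule_Name = mol$id, Source = "zbscreen", Comment = "",
              Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  methods::new("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = character(0))
}

# Fixed-width V2000 molblock text (ChemmineR's writer mis-formats all-zero
# coordinate columns, which Open Babel then rejects, so serialization for
# format conversion goes through this formatter).
mol_molblock <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  xyz <- if (!is.null(mol$coords)) mol$coords else matrix(0, n, 3)
  code <- MDL_CHARGE_CODE[as.character(mol$atoms$charge)]
  code[is.na(code)] <- 0L
  atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s%2d%3d  0  0  0  0  0  0  0  0  0  0",
                        xyz[, 1], xyz[, 2], xyz[, 3], mol$atoms$element, 0L, code)
  bond_lines <- if (nb) sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$a1,
                                mol$bonds$a2, mol$bonds$order) else character(0)
  c(mol$id, " zbscreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
    atom_lines, bond_lines, "M  END", "$$$$")
}

mols_to_sdfset <- function(mols) {
  sdfs <- lapply(mols, mol_to_sdf)
  methods::new("SDFset", SDF = sdfs,
               ID = vapply(mols, function(m) m$id, character(1)))
}

sdf_to_mol <- function(sdf, id, source = "sdf") {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  el <- sub("_.*$", "", rownames(ab))
  code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  chmap <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  ch <- chmap[as.character(code)]
  ch[is.na(ch)] <- 0L
  coords <- NULL
  if (n > 0 && any(abs(ab[, 3]) > 1e-8)) coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0)
    NULL else data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  mol_record(id, data.frame(element = el, charge = ch), bonds,
             coords = coords, source = source)
}

# ---- SMILES round trips through Open Babel ------------------------------

# Parse multi-record SDF text into mol_records. ChemmineR handles the
# general case; records without bonds (single atoms), which ChemmineR
# rejects as invalid, fall back to a direct read of their V2000 atom lines.
parse_sdf_text <- function(sdftxt, source = "sdf", default_ids = NULL) {
  lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  out <- list()
  for (i in seq_along(ends)) {
    rec <- lines[starts[i]:ends[i]]
    rec <- rec[cumsum(trimws(rec) != "") > 0]   # strip leading blanks
    if (length(rec) < 4) next
    nm <- trimws(rec[1])
    if (!nzchar(nm)) nm <- if (!is.null(default_ids) && i <= length(default_ids))
      default_ids[i] else paste0("mol", i)
    na <- suppressWarnings(as.integer(substr(rec[4], 1, 3)))
    nb <- suppressWarnings(as.integer(substr(rec[4], 4, 6)))
    if (is.na(na) || na == 0) next
    m <- if (!is.na(nb) && nb > 0) {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(
        ChemmineR::read.SDFstr(textConnection(
          paste(c(rec[-length(rec)], "$$$$"), collapse = "\n")))))
      if (!suppressWarnings(ChemmineR::validSDF(sdfset))[1]) NULL
      else tryCatch(sdf_to_mol(sdfset[[1]], nm, source = source),
                    error = function(e) NULL)
    } else {
      atom_lines <- rec[5:(4 + na)]
      el <- trimws(substr(atom_lines, 32, 34))
      code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
      chmap <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
      ch <- unname(chmap[as.character(code)]); ch[is.na(ch)] <- 0L
      xyz <- matrix(c(as.numeric(substr(atom_lines, 1, 10)),
                      as.numeric(substr(atom_lines, 11, 20)),
                      as.numeric(substr(atom_lines, 21, 30))), ncol = 3)
      mol_record(nm, data.frame(element = el, charge = ch), NULL,
                 coords = if (any(abs(xyz[, 3]) > 1e-8)) xyz else NULL,
                 source = source)
    }
    if (!is.null(m)) out[[length(out) + 1]] <- m
  }
  out
}

#' Parse SMILES strings into molecule records
#'
#' @param smiles character vector of SMILES.
#' @param ids optional ids (defaults to `mol1`, `mol2`, ...).
#' @return list of `mol_record`.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  txt <- paste0(paste(smiles, ids, sep = "\t"), "\n", collapse = "")
  sdfstr <- ChemmineOB::convertFormat("SMI", "SDF", source = txt)
  parse_sdf_text(sdfstr, source = "smiles", default_ids = ids)
}

mol_to_smiles <- function(mol, canonical = FALSE) {
  sdftxt <- paste(c(mol_molblock(mol), ""), collapse = "\n")
  out <- ChemmineOB::convertFormat("SDF", if (canonical) "CAN" else "SMI",
                                   source = sdftxt)
  sub("\t.*$", "", strsplit(out, "\n")[[1]][1])
}

#' Canonical structure key
#'
#' Canonical SMILES (Open Babel canonicalization) including formal charges,
#' suffixed with any assigned stereo labels. Used as the deduplication key.
#'
#' @param mol a `mol_record`.
#' @return character key.
#' @export
canonical_key <- function(mol) {
  key <- mol_to_smiles(mol, canonical = TRUE)
  if (!is.null(mol$stereo) && nrow(mol$stereo))
    key <- paste0(key, "|", paste(mol$stereo$atom, mol$stereo$config,
                                  sep = ":", collapse = ","))
  key
}

#' Canonical structure keys for a whole collection
#'
#' Batched variant of [canonical_key()] (one Open Babel call for the whole
#' collection); records the converter cannot align fall back to the
#' per-record path.
#' @param mols list of `mol_record`.
#' @return character vector of keys.
#' @export
canonical_keys <- function(mols) {
  if (!length(mols)) return(character(0))
  tags <- sprintf("zbk%06d", seq_along(mols))
  blocks <- unlist(lapply(seq_along(mols), function(i) {
    m <- mols[[i]]; m$id <- tags[i]; mol_molblock(m)
  }))
  out <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN",
                              source = paste(c(blocks, ""), collapse = "\n")),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- stats::setNames(vapply(parts, `[`, character(1), 1),
                         trimws(vapply(parts, function(p)
                           if (length(p) >= 2) p[2] else "", character(1))))
  keys <- unname(smi[tags])
  miss <- which(is.na(keys))
  for (i in miss) keys[i] <- mol_to_smiles(mols[[i]], canonical = TRUE)
  stereo_sfx <- vapply(mols, function(m)
    if (!is.null(m$stereo) && nrow(m$stereo))
      paste0("|", paste(m$stereo$atom, m$stereo$config, sep = ":",
                        collapse = ",")) else "", character(1))
  paste0(keys, stereo_sfx)
}

# ---- file I/O -----------------------------------------------------------

#' Read a compound library
#'
#' Reads SMILES (`.smi`: whitespace-separated "SMILES id" per line) or SDF
#' V2000 files, transparently gunzipping `.gz` paths. Unparseable entries are
#' skipped with a warning and counted in the `skipped` attribute.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @return list of `mol_record` with attribute `skipped`.
#' @export
read_molecules <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  base <- sub("\\.gz$", "", path)
  if (format == "auto")
    format <- if (grepl("\\.(sdf|mol)$", base, ignore.case = TRUE)) "sdf" else "smiles"
  if (format == "smiles") {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("zero parseable records in ", path)
    parts <- strsplit(trimws(lines), "[ \t]+")
    smi <- vapply(parts, `[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i), character(1))
    out <- list(); skipped <- 0L
    for (i in seq_along(smi)) {
      m <- tryCatch(parse_smiles(smi[i], ids[i])[[1]], error = function(e) NULL)
      ok <- !is.null(m) && n_atoms(m) > 0 &&
        tryCatch({ validate_mol(m); TRUE }, error = function(e) FALSE)
      if (ok) out[[length(out) + 1]] <- m
      else { skipped <- skipped + 1L
             warning("skipping unparseable record at line ", i, ": ", smi[i],
                     call. = FALSE) }
    }
  } else {
    lines <- if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rt"); on.exit(close(con)); readLines(con, warn = FALSE)
    } else readLines(path, warn = FALSE)
    n_rec <- sum(trimws(lines) == "$$$$")
    out <- parse_sdf_text(paste(lines, collapse = "\n"))
    skipped <- n_rec - length(out)
    if (skipped > 0)
      warning(skipped, " invalid SDF record(s) skipped", call. = FALSE)
  }
  if (!length(out)) stop("zero parseable records in ", path)
  attr(out, "skipped") <- skipped
  out
}

#' Write a compound library
#'
#' @param mols list of `mol_record`.
#' @param path output path (`.smi` or `.sdf`, `.gz` for gzip).
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @export
write_molecules <- function(mols, path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  base <- sub("\\.gz$", "", path)
  if (format == "auto")
    format <- if (grepl("\\.(sdf|mol)$", base, ignore.case = TRUE)) "sdf" else "smiles"
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (format == "smiles") {
    for (m in mols) writeLines(paste(mol_to_smiles(m), m$id), con)
  } else {
    for (m in mols) writeLines(mol_molblock(m), con)
  }
  invisible(path)
}
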