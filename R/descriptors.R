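# Physicochemical descriptors.
#
# Two hydrogen-bond conventions are in play in this package and they are
# deliberately distinct:
#   * the Lipinski convention used by the drug-likeness filters (donors =
#     count of N-H and O-H hydrogens, acceptors = count of N and O atoms),
#     computed here from the molecular graph;
#   * the pharmacophore-perception donors/acceptors (see
#     perceive_ligand_features), which are geometric feature points.
# logP and TPSA come from Open Babel's published atom-contribution schemes
# (Wildman-Crippen logP, Ertl TPSA) via ChemmineOB; molecular weight is the
# sum of standard atomic masses including implicit hydrogens.

#' Compute physicochemical descriptors
#'
#' Returns, per molecule: molecular weight (g/mol), estimated logP, Lipinski
#' hydrogen-bond donor and acceptor counts, rotatable-bond count and topological
#' polar surface area (A^2).
#'
#' Rotatable bonds are acyclic single bonds between two non-terminal heavy
#' atoms, excluding amide C-N bonds; terminal O-H/N-H groups are therefore
#' never counted.
#'
#' @param mols a `mol_record` or list of them.
#' @return data.frame with columns `id`, `mw`, `clogp`, `hbd`, `hba`, `rotb`,
#'   `tpsa`.
#' @export
compute_descriptors <- function(mols) {
  if (inherits(mols, "mol_record")) mols <- list(mols)
  for (m in mols) validate_mol(m)
  sdfset <- mols_to_sdfset(mols)
  props <- ChemmineR::propOB(sdfset)
  out <- data.frame(
    id = vapply(mols, function(m) m$id, character(1)),
    mw = vapply(mols, mol_weight, numeric(1)),
    clogp = as.numeric(props$logP),
    hbd = vapply(mols, count_hbd, numeric(1)),
    hba = vapply(mols, count_hba, numeric(1)),
    rotb = vapply(mols, count_rotatable, numeric(1)),
    tpsa = as.numeric(props$TPSA)
  )
  rownames(out) <- NULL
  out
}

mol_weight <- function(mol) {
  if (n_atoms(mol) == 0) return(0)
  m <- ATOMIC_MASS[mol$atoms$element]
  if (anyNA(m)) stop("unknown element in molecule '", mol$id, "'")
  sum(m) + sum(implicit_h(mol)) * ATOMIC_MASS[["H"]]
}

# Lipinski donors: total N-H and O-H hydrogens
count_hbd <- function(mol) {
  h <- implicit_h(mol)
  sum(h[mol$atoms$element %in% c("N", "O")])
}

# Lipinski acceptors: count of N and O atoms
count_hba <- function(mol) sum(mol$atoms$element %in% c("N", "O"))

count_rotatable <- function(mol) {
  b <- mol$bonds
  if (!nrow(b)) return(0L)
  deg <- heavy_degree(mol)
  ring <- ring_atoms(mol)
  in_ring_bond <- function(i) {
    rings <- mol_rings(mol)
    any(vapply(rings, function(r) b$a1[i] %in% r && b$a2[i] %in% r, logical(1)))
  }
  rings <- mol_rings(mol)
  adj <- mol_adj(mol)
  is_amide_cn <- function(a1, a2) {
    for (pair in list(c(a1, a2), c(a2, a1))) {
      cC <- pair[1]; nN <- pair[2]
      if (mol$atoms$element[cC] == "C" && mol$atoms$element[nN] == "N" &&
          any(adj[[cC]]$order == 2 &
              mol$atoms$element[adj[[cC]]$nbr] == "O")) return(TRUE)
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(nrow(b))) {
    if (b$order[i] != 1L) next
    a1 <- b$a1[i]; a2 <- b$a2[i]
    if (deg[a1] < 2 || deg[a2] < 2) next
    if (any(vapply(rings, function(r) a1 %in% r && a2 %in% r, logical(1)))) next
    if (is_amide_cn(a1, a2)) next
    cnt <- cnt + 1L
  }
  cnt
}
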