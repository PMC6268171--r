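# Receptor-ligand pharmacophore perception: re-derive interaction features
# from a 3D complex using transparent geometric rules.
#
# Interaction rules (heavy-atom geometry):
#   hydrogen bond      donor-acceptor distance <= 3.5 A and an angle of at
#                      least 120 degrees at the donor (measured through the
#                      donor's bonded heavy neighbour; donors without
#                      neighbours pass the angle check);
#   hydrophobic        ligand apolar carbon within 4.5 A of a receptor
#                      side-chain carbon of a hydrophobic residue, clustered
#                      into contiguous ligand patches;
#   charge pair        ligand ionizable group centroid within 5.5 A of a
#                      charged receptor group;
#   metal coordination ligand N/O within 2.8 A of the zinc, emitted as the
#                      zinc-oriented HBD candidate that customize_zb()
#                      re-types to ZB (zinc-coordinating atoms are excluded
#                      from ordinary hydrogen-bond perception).
# Features sit on the ligand side with a projection to the receptor partner
# and are annotated with the receptor residue; default tolerance 1.6 A
# (2.2 A for HY).

HYDROPHOBIC_RES <- c("ALA", "VAL", "LEU", "ILE", "PHE", "MET", "TRP", "PRO")

# classify receptor atoms from a bio3d pdb object
receptor_atom_table <- function(pdb) {
  at <- pdb$atom
  xyz <- as.matrix(at[, c("x", "y", "z")])
  elety <- trimws(at$elety)
  resid <- trimws(at$resid)
  elem <- substr(elety, 1, 1)
  data.frame(
    elety = elety, resid = resid, resno = at$resno,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_zn = resid == "ZN" | toupper(elety) == "ZN",
    acceptor = elem == "O",
    donor = elem == "N" |
      (elety %in% c("OG", "OG1", "OH") & resid %in% c("SER", "THR", "TYR")),
    apolar = elem == "C" & resid %in% HYDROPHOBIC_RES &
      !(elety %in% c("C", "CA")),
    pos_charged = (resid == "LYS" & elety == "NZ") |
      (resid == "ARG" & elety %in% c("NE", "NH1", "NH2", "CZ")),
    neg_charged = (resid == "ASP" & elety %in% c("OD1", "OD2")) |
      (resid == "GLU" & elety %in% c("OE1", "OE2")),
    stringsAsFactors = FALSE
  )
}

#' Perceive a receptor-ligand pharmacophore model
#'
#' Derives one candidate feature per detected receptor-ligand interaction
#' (see the rules documented on this file) and assembles them into a
#' pharmacophore model whose metadata records the zinc position when a zinc
#' ion is present. Run [customize_zb()] afterwards to re-type the
#' zinc-oriented donor candidate into the ZB feature.
#'
#' @param receptor path to a PDB file or a `bio3d` pdb object.
#' @param ligand a `mol_record` with 3D coordinates in the receptor frame.
#' @param tolerance feature sphere radius (default 1.6 A; HY uses 2.2).
#' @param min_required minimum match size recorded on the model (default:
#'   the smaller of 4 and the feature count).
#' @return `ph_model` (empty model with a warning when no interaction is
#'   found).
#' @export
perceive_complex_pharmacophore <- function(receptor, ligand, tolerance = 1.6,
                                           min_required = NULL) {
  if (is.character(receptor)) receptor <- bio3d::read.pdb(receptor)
  rec <- receptor_atom_table(receptor)
  if (is.null(ligand$coords)) stop("ligand must carry 3D coordinates")
  xyz <- ligand$coords
  el <- ligand$atoms$element
  h <- implicit_h(ligand)
  ch <- ligand$atoms$charge
  adj <- mol_adj(ligand)
  rings <- mol_rings(ligand)
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  feats <- list()
  fid <- 0L
  add_feat <- function(kind, center, proj_target, annot, tol = tolerance) {
    fid <<- fid + 1L
    feats[[fid]] <<- ph_feature(sprintf("%s%d", kind, fid), kind, center, tol,
      projection = if (kind %in% DIRECTIONAL_KINDS && !is.null(proj_target))
        list(target = proj_target, angle_tol = 45) else NULL,
      annotation = annot)
  }
  res_label <- function(i) paste0(rec$resid[i], rec$resno[i])

  # --- zinc coordination -------------------------------------------------
  zn_idx <- which(rec$is_zn)
  zn <- if (length(zn_idx)) as.numeric(rxyz[zn_idx[1], ]) else NULL
  zinc_coord_atoms <- integer(0)
  if (!is.null(zn)) {
    for (i in which(el %in% c("N", "O"))) {
      if (vnorm(xyz[i, ] - zn) <= 2.8) {
        zinc_coord_atoms <- c(zinc_coord_atoms, i)
        add_feat("HBD", xyz[i, ], zn, "Zn")
      }
    }
  }
  # --- hydrogen bonds ----------------------------------------------------
  donor_angle_ok <- function(i, partner) {
    nb <- adj[[i]]$nbr
    if (!length(nb)) return(TRUE)
    v1 <- xyz[nb[1], ] - xyz[i, ]
    v2 <- partner - xyz[i, ]
    ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))))
    ang * 180 / pi >= 120
  }
  lig_donors <- setdiff(which(el %in% c("N", "O") & h > 0), zinc_coord_atoms)
  lig_acceptors <- setdiff(which((el == "O" & ch <= 0) |
                                 (el == "N" & h == 0 & ch <= 0)),
                           zinc_coord_atoms)
  for (i in lig_donors) {
    dists <- dist_to(xyz[i, ], rxyz)
    for (j in which(rec$acceptor & !rec$is_zn & dists <= 3.5))
      if (donor_angle_ok(i, as.numeric(rxyz[j, ])))
        add_feat("HBD", xyz[i, ], as.numeric(rxyz[j, ]), res_label(j))
  }
  for (i in lig_acceptors) {
    dists <- dist_to(xyz[i, ], rxyz)
    for (j in which(rec$donor & !rec$is_zn & dists <= 3.5))
      add_feat("HBA", xyz[i, ], as.numeric(rxyz[j, ]), res_label(j))
  }
  # --- hydrophobic contacts ---------------------------------------------
  in_ring <- seq_len(n_atoms(ligand)) %in% unlist(rings)
  apolar_lig <- which(vapply(seq_len(n_atoms(ligand)), function(i)
    el[i] == "C" && ch[i] == 0 && all(el[adj[[i]]$nbr] %in% c("C", "H")),
    logical(1)))
  contact <- apolar_lig[vapply(apolar_lig, function(i)
    any(rec$apolar & dist_to(xyz[i, ], rxyz) <= 4.5), logical(1))]
  if (length(contact)) {
    # cluster contiguous (bonded) contact atoms into patches
    left <- contact
    while (length(left)) {
      patch <- left[1]; left <- left[-1]
      repeat {
        grow <- left[vapply(left, function(a)
          any(adj[[a]]$nbr %in% patch), logical(1))]
        if (!length(grow)) break
        patch <- c(patch, grow); left <- setdiff(left, grow)
      }
      nearest <- which(rec$apolar)[which.min(
        dist_to(colMeans(xyz[patch, , drop = FALSE]),
                rxyz[rec$apolar, , drop = FALSE]))]
      add_feat("HY", colMeans(xyz[patch, , drop = FALSE]), NULL,
               res_label(nearest), tol = 2.2)
    }
  }
  # --- charge pairs ------------------------------------------------------
  ctx <- list(adj = adj, h = h, el = el, ch = ch,
              deg = heavy_degree(ligand), rings = rings,
              arom = aromatic_rings(ligand))
  ni_groups <- c(lapply(zbg_carboxyl(ligand, ctx), `[[`, "coordinating"),
                 lapply(zbg_phosphate(ligand, ctx), `[[`, "coordinating"))
  for (g in ni_groups) {
    cen <- colMeans(xyz[g, , drop = FALSE])
    js <- which(rec$pos_charged & dist_to(cen, rxyz) <= 5.5)
    if (length(js)) add_feat("NI", cen, NULL, res_label(js[1]))
  }
  pi_atoms <- which(el == "N" & ch > 0)
  for (i in pi_atoms) {
    js <- which(rec$neg_charged & dist_to(xyz[i, ], rxyz) <= 5.5)
    if (length(js)) add_feat("PI", xyz[i, ], NULL, res_label(js[1]))
  }
  if (!length(feats)) {
    warning("no receptor-ligand interactions found: empty model", call. = FALSE)
    return(ph_model(list(), 0L, metadata = list(zinc = zn), name = "perceived"))
  }
  ph_model(feats, min_required %||% min(4L, length(feats)),
           metadata = list(source_structure = "complex", zinc = zn),
           name = "perceived")
}
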