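# Rule-based annotation of noncovalent protein-ligand interactions and the
# per-Type interaction-preference matrix. Hydrogen positions are not modeled:
# donor capacity is inferred from heavy-atom chemistry (backbone N donates,
# backbone O accepts, side chains per a residue chemistry table).

INTERACTION_KINDS <- c("hydrogen_bond", "salt_bridge", "pi_stacking",
                       "pi_cation", "hydrophobic", "metal_complex")

#' Default geometric cutoffs for interaction detection
#'
#' All distances in Angstrom, angles in degrees. Every value can be
#' overridden via the \code{config} argument of
#' \code{\link{annotate_interactions}} or the pipeline configuration file.
#'
#' @return named list of cutoffs.
#' @export
default_interaction_config <- function() {
  list(
    hbond_dist = 4.1,        # donor-acceptor heavy-atom distance
    hbond_donor_angle = 100, # neighbor-donor-acceptor angle proxy
    saltbridge_dist = 5.5,   # charged-group centroid distance
    pication_dist = 6.0,     # cation to aromatic ring centroid
    pistack_dist = 5.5,      # ring centroid distance
    pistack_parallel = 30,   # plane angle for parallel stacking
    pistack_perp = c(60, 90),# plane angle window for T-stacking
    hydrophobic_dist = 4.0,  # apolar carbon-carbon distance
    metal_dist = 3.0,        # metal to coordinating atom
    neighborhood = 10.0      # coarse residue prefilter
  )
}

# Side-chain hydrogen-bond chemistry of the standard residues.
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"), TRP = "NE1"
)
SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"),
  MET = "SD"
)
POSITIVE_GROUPS <- list(
  ARG = c("CZ", "NE", "NH1", "NH2"), LYS = "NZ",
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
NEGATIVE_GROUPS <- list(
  ASP = c("CG", "OD1", "OD2"), GLU = c("CD", "OE1", "OE2")
)
AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

residue_atoms_xyz <- function(residue, names) {
  i <- match(names, residue$atoms$name)
  i <- i[!is.na(i)]
  if (length(i) == 0) return(NULL)
  atom_xyz(residue$atoms)[i, , drop = FALSE]
}

plane_normal <- function(xyz) {
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  sv$v[, 3]
}

ring_planarity <- function(xyz) {
  c0 <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, c0))
  max(abs(sweep(xyz, 2, c0) %*% sv$v[, 3]))
}

# Chemistry of the ligand derived from its bond graph.
ligand_chemistry <- function(ligand) {
  atoms <- ligand$atoms
  n <- nrow(atoms)
  bonds <- infer_bonds(atoms)
  m <- ligand_moieties(atoms, bonds)
  nb <- m$neighbors
  deg <- lengths(nb)
  elem <- atoms$element
  xyz <- atom_xyz(atoms)
  bond_len <- function(i, j) vnorm(xyz[i, ] - xyz[j, ])

  phosphate_o <- intersect(m$phosphate, which(elem == "O"))
  acceptor <- elem %in% c("O", "N")
  # ring N with three heavy neighbors (e.g. substituted N9) has no lone pair
  # geometry we trust; N donors are those with implicit hydrogens (degree < 3)
  donor <- logical(n)
  donor[elem == "N" & deg < 3] <- TRUE
  for (i in which(elem == "O" & deg == 1)) {
    j <- nb[[i]][1]
    if (!is.na(j) && elem[j] == "C" && bond_len(i, j) >= 1.3)
      donor[i] <- TRUE   # hydroxyl-like
  }
  donor[phosphate_o] <- FALSE
  acceptor[elem == "N" & deg >= 3] <- FALSE

  # charged groups
  neg_groups <- list()
  for (p in intersect(m$phosphate, which(elem == "P")))
    neg_groups[[length(neg_groups) + 1]] <-
      c(p, intersect(nb[[p]], which(elem == "O")))
  for (cc in which(elem == "C")) {
    ox <- intersect(nb[[cc]], which(elem == "O" & deg == 1))
    ox <- setdiff(ox, phosphate_o)
    if (length(ox) == 2)
      neg_groups[[length(neg_groups) + 1]] <- c(cc, ox)
  }
  pos_groups <- list()
  for (nn in which(elem == "N" & deg == 1)) {
    j <- nb[[nn]][1]
    if (!is.na(j) && elem[j] == "C" && !(j %in% unlist(neg_groups)) &&
        length(intersect(nb[[j]], which(elem == "O"))) == 0 &&
        !(j %in% m$adenine))
      pos_groups[[length(pos_groups) + 1]] <- nn
  }

  # aromatic rings: 5/6-membered all-C/N rings that are nearly planar
  rings <- Filter(function(rg) length(rg) >= 5 &&
                    all(elem[rg] %in% c("C", "N")) &&
                    ring_planarity(xyz[rg, , drop = FALSE]) < 0.25,
                  m$rings)
  apolar <- elem == "C" &
    vapply(seq_len(n), function(i)
      !any(elem[nb[[i]]] %in% c("N", "O", "S", "P")), TRUE)

  list(bonds = bonds, neighbors = nb, moieties = m, donor = donor,
       acceptor = acceptor, neg_groups = neg_groups,
       pos_groups = pos_groups, rings = rings, apolar = apolar, xyz = xyz)
}

#' Attribute ligand atoms to fragments
#'
#' Partitions a nucleotide-containing ligand's atoms into \code{phosphate}
#' (P and its bonded oxygens), \code{adenine} (the fused-ring atoms plus
#' their terminal substituents, e.g. the exocyclic N6), \code{ribose} (the
#' five-ring with its exocyclic carbons/oxygens) and
#' \code{amino_acid_part} (the remainder). Non-nucleotide ligands are
#' entirely \code{amino_acid_part}.
#'
#' @param ligand an \code{\link{new_ligand}} record.
#' @param chem optional precomputed \code{ligand_chemistry}.
#' @return character vector of fragment labels, one per atom.
#' @export
assign_fragment <- function(ligand, chem = NULL) {
  atoms <- ligand$atoms
  if (is.null(chem)) chem <- ligand_chemistry(ligand)
  m <- chem$moieties
  n <- nrow(atoms)
  lab <- rep("amino_acid_part", n)
  if (length(m$adenine) == 0 || length(m$ribose) == 0)
    return(lab)
  assigned <- logical(n)
  take <- function(idx, what) {
    idx <- setdiff(idx, which(assigned))
    lab[idx] <<- what
    assigned[idx] <<- TRUE
  }
  take(m$phosphate, "phosphate")
  ade_sub <- which(vapply(seq_len(n), function(i)
    !assigned[i] && !(i %in% m$adenine) &&
      length(chem$neighbors[[i]]) >= 1 &&
      all(chem$neighbors[[i]] %in% m$adenine), TRUE))
  take(c(m$adenine, ade_sub), "adenine")
  rib_sub <- which(vapply(seq_len(n), function(i)
    !assigned[i] && !(i %in% m$ribose) &&
      atoms$element[i] %in% c("C", "O") &&
      any(chem$neighbors[[i]] %in% m$ribose), TRUE))
  rib_sub2 <- which(vapply(seq_len(n), function(i)
    !assigned[i] && atoms$element[i] == "O" && !(i %in% rib_sub) &&
      any(chem$neighbors[[i]] %in% rib_sub), TRUE))
  take(c(m$ribose, rib_sub, rib_sub2), "ribose")
  lab
}

residue_bonds_cache <- function(residue) {
  infer_bonds(residue$atoms)
}

# apolar side-chain carbons of a residue (no N/O/S/P neighbor)
residue_apolar <- function(residue, bonds) {
  elem <- residue$atoms$element
  n <- nrow(residue$atoms)
  nb <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))
  which(elem == "C" &
          vapply(seq_len(n), function(i)
            length(nb[[i]]) > 0 &&
              !any(elem[nb[[i]]] %in% c("N", "O", "S", "P")), TRUE))
}

#' Annotate noncovalent interactions between a chain and one ligand
#'
#' Applies explicit geometric rules (see
#' \code{\link{default_interaction_config}}): hydrogen bonds (heavy-atom
#' donor-acceptor distance with a donor-angle proxy), salt bridges
#' (charged-group centroid distance), pi-cation, pi-stacking (parallel or
#' perpendicular ring planes), hydrophobic contacts (apolar carbon pairs)
#' and metal complexes (a metal ion bridging within the cutoff of a ligand
#' atom). Hydrogen bonds between atom groups already forming a recorded salt
#' bridge are suppressed, and records are deduplicated to one per
#' (residue, kind, fragment) keeping the shortest distance.
#'
#' @param chain a (typically renumbered) \code{\link{structure_chain}}.
#' @param ligand the ligand record to profile (one of \code{chain$ligands}).
#' @param config cutoff list, see \code{\link{default_interaction_config}}.
#' @param metals optional list of additional single-atom metal ligand records
#'   to consider for metal complexes; defaults to the chain's own single-atom
#'   metal ligands.
#' @return data.frame with one row per interaction record: \code{kind},
#'   \code{res_number}, \code{res_icode}, \code{res_name}, \code{backbone},
#'   \code{fragment}, \code{distance}, \code{angle}.
#' @export
annotate_interactions <- function(chain, ligand,
                                  config = default_interaction_config(),
                                  metals = NULL) {
  cfg <- utils::modifyList(default_interaction_config(), config)
  atoms <- ligand$atoms
  small <- nrow(atoms) < 3
  chem <- ligand_chemistry(ligand)
  frag <- assign_fragment(ligand, chem)
  lxyz <- chem$xyz

  rec <- list()
  add <- function(kind, res, backbone, fragment, distance, angle = NA_real_,
                  patom = NA, latom = NA) {
    rec[[length(rec) + 1]] <<- data.frame(
      kind = kind, res_number = res$number, res_icode = res$icode,
      res_name = res$name, backbone = backbone, fragment = fragment,
      distance = distance, angle = angle, protein_atom = patom,
      ligand_atom = latom, stringsAsFactors = FALSE)
  }

  # ligand rings / groups (suppressed for tiny ligands)
  lig_rings <- if (small) list() else chem$rings
  lig_neg <- if (small) list() else chem$neg_groups
  lig_pos <- if (small) list() else chem$pos_groups

  for (res in polymer_residues(chain)) {
    rxyz <- atom_xyz(res$atoms)
    dmin2 <- min(outer(rowSums(rxyz^2), rowSums(lxyz^2), "+") -
                   2 * rxyz %*% t(lxyz))
    if (dmin2 > cfg$neighborhood^2) next
    bonds <- residue_bonds_cache(res)
    nbres <- lapply(seq_len(nrow(res$atoms)), function(i)
      c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))

    # --- salt bridges (recorded first so they can suppress hydrogen bonds)
    sb_pairs <- list()
    pgroups <- POSITIVE_GROUPS[[res$name]]
    ngroups <- NEGATIVE_GROUPS[[res$name]]
    if (!is.null(pgroups)) {
      gx <- residue_atoms_xyz(res, pgroups)
      if (!is.null(gx)) {
        cen <- colMeans(gx)
        for (gi in seq_along(lig_neg)) {
          lcen <- colMeans(lxyz[lig_neg[[gi]], , drop = FALSE])
          d <- vnorm(cen - lcen)
          if (d <= cfg$saltbridge_dist) {
            fr <- names(sort(table(frag[lig_neg[[gi]]]), decreasing = TRUE))[1]
            add("salt_bridge", res, FALSE, fr, d)
            sb_pairs[[length(sb_pairs) + 1]] <-
              list(protein = pgroups, ligand = lig_neg[[gi]])
          }
        }
      }
    }
    if (!is.null(ngroups)) {
      gx <- residue_atoms_xyz(res, ngroups)
      if (!is.null(gx)) {
        cen <- colMeans(gx)
        for (gi in seq_along(lig_pos)) {
          lcen <- colMeans(lxyz[lig_pos[[gi]], , drop = FALSE])
          d <- vnorm(cen - lcen)
          if (d <= cfg$saltbridge_dist) {
            fr <- names(sort(table(frag[lig_pos[[gi]]]), decreasing = TRUE))[1]
            add("salt_bridge", res, FALSE, fr, d)
            sb_pairs[[length(sb_pairs) + 1]] <-
              list(protein = ngroups, ligand = lig_pos[[gi]])
          }
        }
      }
    }
    suppressed <- function(pname, lidx) {
      for (sb in sb_pairs)
        if (pname %in% sb$protein && lidx %in% sb$ligand) return(TRUE)
      FALSE
    }

    # --- hydrogen bonds
    donors <- character(0)
    if (res$name != "PRO") donors <- "N"
    donors <- c(donors, intersect(SIDECHAIN_DONORS[[res$name]] %||% character(0),
                                  res$atoms$name))
    acceptors <- intersect(c("O", "OXT",
                             SIDECHAIN_ACCEPTORS[[res$name]] %||% character(0)),
                           res$atoms$name)
    donor_angle_ok <- function(didx, target) {
      nbi <- nbres[[didx]]
      if (length(nbi) == 0) return(TRUE)
      dpos <- rxyz[didx, ]
      any(vapply(nbi, function(j)
        angle_between(rxyz[j, ] - dpos, target - dpos) >=
          cfg$hbond_donor_angle, TRUE))
    }
    for (dn in intersect(donors, res$atoms$name)) {
      didx <- match(dn, res$atoms$name)
      for (ai in which(chem$acceptor)) {
        d <- vnorm(rxyz[didx, ] - lxyz[ai, ])
        if (d <= cfg$hbond_dist && d > 1.8 && !suppressed(dn, ai) &&
            donor_angle_ok(didx, lxyz[ai, ])) {
          add("hydrogen_bond", res, dn %in% BACKBONE_ATOMS, frag[ai], d,
              patom = dn, latom = atoms$name[ai])
        }
      }
    }
    for (an in acceptors) {
      aidx <- match(an, res$atoms$name)
      for (di in which(chem$donor)) {
        d <- vnorm(rxyz[aidx, ] - lxyz[di, ])
        if (d <= cfg$hbond_dist && d > 1.8 && !suppressed(an, di)) {
          # donor-angle proxy on the ligand donor
          nbl <- chem$neighbors[[di]]
          ok <- length(nbl) == 0 ||
            any(vapply(nbl, function(j)
              angle_between(lxyz[j, ] - lxyz[di, ],
                            rxyz[aidx, ] - lxyz[di, ]) >=
                cfg$hbond_donor_angle, TRUE))
          if (ok)
            add("hydrogen_bond", res, an %in% BACKBONE_ATOMS, frag[di], d,
                patom = an, latom = atoms$name[di])
        }
      }
    }

    # --- pi-cation
    if (!is.null(pgroups)) {
      gx <- residue_atoms_xyz(res, pgroups)
      if (!is.null(gx)) {
        cen <- colMeans(gx)
        for (rg in lig_rings) {
          rc <- colMeans(lxyz[rg, , drop = FALSE])
          d <- vnorm(cen - rc)
          if (d <= cfg$pication_dist) {
            fr <- names(sort(table(frag[rg]), decreasing = TRUE))[1]
            add("pi_cation", res, FALSE, fr, d)
          }
        }
      }
    }
    ring_names <- AROMATIC_RINGS[[res$name]]
    if (!is.null(ring_names)) {
      rx <- residue_atoms_xyz(res, ring_names)
      if (!is.null(rx) && nrow(rx) >= 5) {
        rcen <- colMeans(rx)
        for (gi in seq_along(lig_pos)) {
          d <- vnorm(rcen - lxyz[lig_pos[[gi]], ])
          if (d <= cfg$pication_dist)
            add("pi_cation", res, FALSE, frag[lig_pos[[gi]]], d)
        }
        # --- pi-stacking
        for (rg in lig_rings) {
          rc <- colMeans(lxyz[rg, , drop = FALSE])
          d <- vnorm(rcen - rc)
          if (d <= cfg$pistack_dist) {
            ang <- angle_between(plane_normal(rx),
                                 plane_normal(lxyz[rg, , drop = FALSE]))
            ang <- min(ang, 180 - ang)
            if (ang < cfg$pistack_parallel ||
                (ang >= cfg$pistack_perp[1] && ang <= cfg$pistack_perp[2])) {
              fr <- names(sort(table(frag[rg]), decreasing = TRUE))[1]
              add("pi_stacking", res, FALSE, fr, d, angle = ang)
            }
          }
        }
      }
    }

    # --- hydrophobic contacts
    ap <- residue_apolar(res, bonds)
    if (length(ap) && any(chem$apolar)) {
      for (i in ap) for (j in which(chem$apolar)) {
        d <- vnorm(rxyz[i, ] - lxyz[j, ])
        if (d <= cfg$hydrophobic_dist && d > 1.9)
          add("hydrophobic", res, FALSE, frag[j], d)
      }
    }
  }

  # --- metal complexes
  if (is.null(metals))
    metals <- Filter(function(l) nrow(l$atoms) == 1 &&
                       l$atoms$element[1] %in% METAL_ELEMENTS, chain$ligands)
  for (met in metals) {
    if (identical(met, ligand)) next
    mx <- as.numeric(met$atoms[1, c("x", "y", "z")])
    dmat <- sqrt(colSums((t(lxyz) - mx)^2))
    if (any(dmat <= cfg$metal_dist)) {
      j <- which.min(dmat)
      rec[[length(rec) + 1]] <- data.frame(
        kind = "metal_complex", res_number = met$number, res_icode = "",
        res_name = met$component_code, backbone = FALSE, fragment = frag[j],
        distance = dmat[j], angle = NA_real_,
        protein_atom = NA, ligand_atom = atoms$name[j],
        stringsAsFactors = FALSE)
    }
  }

  if (length(rec) == 0)
    return(data.frame(kind = character(0), res_number = integer(0),
                      res_icode = character(0), res_name = character(0),
                      backbone = logical(0), fragment = character(0),
                      distance = numeric(0), angle = numeric(0),
                      protein_atom = character(0),
                      ligand_atom = character(0)))
  out <- do.call(rbind, rec)
  out <- out[order(out$kind, out$res_number, out$fragment, out$distance), ]
  out[!duplicated(out[, c("kind", "res_number", "res_name", "fragment")]), ,
      drop = FALSE]
}

#' Build the per-Type interaction-preference matrix
#'
#' For each (renumbered position, ligand fragment, aaRS type) cell the
#' absolute frequency of each interaction kind is counted over the supplied
#' M1 representative complexes; the preferred kind(s) are the argmax (two
#' reported on a tie). Positions whose interactions are observed in only one
#' aaRS type are discarded. Chains contributing a position without any
#' record there count toward the cell's \code{no_contact}.
#'
#' @param records data.frame of interaction records with added columns
#'   \code{aars_type} and \code{chain_key}.
#' @param presence data.frame (\code{aars_type}, \code{chain_key},
#'   \code{position}) listing which renumbered positions exist in which
#'   chain; used for no-contact counting. May be NULL.
#' @return data.frame with one row per cell: position, fragment, aars_type,
#'   one count column per kind, no_contact, preferred, preferred2.
#' @export
build_interaction_matrix <- function(records, presence = NULL) {
  if (nrow(records) == 0)
    return(data.frame(position = integer(0), fragment = character(0),
                      aars_type = character(0)))
  records$position <- records$res_number
  types_per_pos <- tapply(records$aars_type, records$position,
                          function(x) length(unique(x)))
  keep <- as.integer(names(types_per_pos)[types_per_pos >= 2])
  records <- records[records$position %in% keep, , drop = FALSE]
  if (nrow(records) == 0)
    return(data.frame(position = integer(0), fragment = character(0),
                      aars_type = character(0)))

  cells <- unique(records[, c("position", "fragment", "aars_type")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- records[records$position == cell$position &
                     records$fragment == cell$fragment &
                     records$aars_type == cell$aars_type, , drop = FALSE]
    counts <- vapply(INTERACTION_KINDS, function(k) sum(sub$kind == k), 0L)
    mx <- max(counts)
    pref <- INTERACTION_KINDS[counts == mx & counts > 0]
    nc <- NA_integer_
    if (!is.null(presence)) {
      have <- presence[presence$aars_type == cell$aars_type &
                         presence$position == cell$position, , drop = FALSE]
      contacted <- unique(sub$chain_key)
      nc <- sum(!have$chain_key %in% unique(
        records$chain_key[records$position == cell$position &
                            records$aars_type == cell$aars_type]))
    }
    cbind(cell,
          as.data.frame(as.list(counts)),
          data.frame(no_contact = nc,
                     preferred = pref[1],
                     preferred2 = if (length(pref) >= 2) pref[2]
                                  else NA_character_,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$position, out$fragment, out$aars_type), ]
}

#' Write interaction records / matrix
#'
#' @param records interaction record data.frame.
#' @param matrix_df matrix data.frame from
#'   \code{\link{build_interaction_matrix}}.
#' @param records_tsv,matrix_tsv,matrix_json output paths (NULL to skip).
#' @return invisibly NULL.
#' @export
write_interaction_reports <- function(records = NULL, matrix_df = NULL,
                                      records_tsv = NULL, matrix_tsv = NULL,
                                      matrix_json = NULL) {
  if (!is.null(records) && !is.null(records_tsv))
    utils::write.table(records, records_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(matrix_df) && !is.null(matrix_tsv))
    utils::write.table(matrix_df, matrix_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(matrix_df) && !is.null(matrix_json))
    jsonlite::write_json(matrix_df, matrix_json, dataframe = "rows",
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}
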