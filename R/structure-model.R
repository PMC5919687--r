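# Typed structure model: chains, residues, atoms and ligand records read from
# (and written back to) fixed-width PDB format.

#' Construct an atom table
#'
#' Atoms are stored as a data.frame with one row per atom: \code{name}
#' (PDB atom label), \code{element} (chemical symbol, upper case) and
#' Cartesian coordinates \code{x,y,z} in Angstrom.
#'
#' @param name character vector of atom labels (e.g. "CA", "NH1").
#' @param element chemical element symbols; guessed from the name if missing.
#' @param x,y,z coordinates in Angstrom.
#' @return data.frame of class \code{aars_atoms}.
#' @export
atom_table <- function(name, element = NULL, x, y, z) {
  if (is.null(element)) element <- vapply(name, guess_element, "")
  element <- toupper(element)
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(is.finite(z)),
            all(nzchar(element)))
  df <- data.frame(name = as.character(name), element = element,
                   x = x, y = y, z = z, stringsAsFactors = FALSE)
  class(df) <- c("aars_atoms", "data.frame")
  df
}

atom_xyz <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Construct a residue
#'
#' @param number author residue number (integer).
#' @param name 3-letter chemical component code.
#' @param atoms an \code{\link{atom_table}}; atom names must be unique.
#' @param icode insertion code ("" if none).
#' @param is_polymer is this a polymer (ATOM-record) residue?
#' @return list of class \code{aars_residue}.
#' @export
new_residue <- function(number, name, atoms, icode = "", is_polymer = TRUE) {
  stopifnot(!anyDuplicated(atoms$name))
  if (is_polymer && sum(atoms$name == "CA" & atoms$element == "C") > 1)
    stop("polymer residue exposes more than one CA atom")
  structure(list(number = as.integer(number), icode = icode,
                 name = toupper(name), atoms = atoms,
                 is_polymer = isTRUE(is_polymer)),
            class = "aars_residue")
}

residue_atom <- function(residue, name) {
  i <- match(name, residue$atoms$name)
  if (is.na(i)) return(NULL)
  as.numeric(residue$atoms[i, c("x", "y", "z")])
}

#' Construct a ligand record
#'
#' Moiety flags (\code{has_adenosine_phosphate}, \code{has_amino_acid_part})
#' are computed from the component code and the inferred atom bond graph via
#' \code{\link{classify_ligand}} unless supplied.
#'
#' @param component_code chemical component ID (e.g. "ATP").
#' @param atoms an \code{\link{atom_table}}.
#' @param number author residue number of the HETATM group.
#' @param chain_id author chain the group was deposited on.
#' @param flags optional precomputed list with both flags.
#' @return list of class \code{aars_ligand}.
#' @export
new_ligand <- function(component_code, atoms, number = 1L, chain_id = "A",
                       flags = NULL) {
  if (is.null(flags)) flags <- classify_ligand(component_code, atoms)
  structure(list(component_code = toupper(component_code),
                 number = as.integer(number), chain_id = chain_id,
                 atoms = atoms,
                 has_adenosine_phosphate = flags$has_adenosine_phosphate,
                 has_amino_acid_part = flags$has_amino_acid_part),
            class = "aars_ligand")
}

#' Construct a structure chain
#'
#' @param structure_id 4-character structure identifier.
#' @param chain_id author chain label.
#' @param residues list of \code{\link{new_residue}} objects, ordered by
#'   author numbering.
#' @param ligands list of \code{\link{new_ligand}} records attached to this
#'   chain.
#' @return list of class \code{aars_chain}.
#' @export
structure_chain <- function(structure_id, chain_id, residues, ligands = list()) {
  num <- vapply(residues, function(r) r$number, 1L)
  if (is.unsorted(num)) {
    ord <- order(num, vapply(residues, function(r) r$icode, ""))
    residues <- residues[ord]
  }
  structure(list(structure_id = structure_id, chain_id = chain_id,
                 residues = residues, ligands = ligands),
            class = "aars_chain")
}

#' @export
print.aars_chain <- function(x, ...) {
  cat(sprintf("<aars_chain %s:%s  %d residues, %d ligand(s)>\n",
              x$structure_id, x$chain_id, length(x$residues),
              length(x$ligands)))
  invisible(x)
}

polymer_residues <- function(chain) {
  chain$residues[vapply(chain$residues, function(r) r$is_polymer, TRUE)]
}

chain_polymer_xyz <- function(chain) {
  res <- polymer_residues(chain)
  if (length(res) == 0) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, lapply(res, function(r) atom_xyz(r$atoms)))
}

# ---------------------------------------------------------------------------
# Parsing

validate_pdb_lines <- function(lines, path) {
  rec <- grep("^(ATOM|HETATM)", lines)
  for (i in rec) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("parse error in '%s' at line %d: record shorter than coordinate fields", path, i))
    coords <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                            substr(ln, 39, 46),
                                            substr(ln, 47, 54))))
    if (anyNA(coords))
      stop(sprintf("parse error in '%s' at line %d: unreadable coordinates", path, i))
  }
  invisible(length(rec))
}

#' Parse a PDB-format file into structure chains
#'
#' Reads fixed-width PDB ATOM/HETATM records. Only the first model of a
#' multi-model (NMR) file is read. For alternate locations the
#' highest-occupancy conformer is kept (ties resolved toward altloc "A").
#' Water molecules are excluded. Every other HETATM group is attached as a
#' ligand record to the chain contributing the most polymer atoms within
#' \code{ligand_contact_cutoff} Angstrom of any ligand atom (ties toward the
#' lexicographically lower chain ID); groups with no chain contact are
#' dropped and reported via the \code{"dropped_ligands"} attribute and a
#' message.
#'
#' @param path path to a PDB-format file.
#' @param structure_id identifier stored on the chains; defaults to the file
#'   base name.
#' @param ligand_contact_cutoff contact distance (Angstrom) for the
#'   ligand-to-chain assignment rule.
#' @return named list of \code{\link{structure_chain}} objects (one per
#'   polymer chain), with attribute \code{dropped_ligands}.
#' @export
parse_structure <- function(path, structure_id = NULL,
                            ligand_contact_cutoff = 4.0) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  if (is.null(structure_id))
    structure_id <- tools::file_path_sans_ext(basename(path))

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("parse error in '%s': %s", path,
                                     conditionMessage(e))))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  at$elesy[is.na(at$elesy) | !nzchar(at$elesy)] <-
    vapply(at$elety[is.na(at$elesy) | !nzchar(at$elesy)], guess_element, "")
  at$elesy <- toupper(trimws(at$elesy))
  at$o[is.na(at$o)] <- 1

  # altloc policy: highest occupancy, ties toward the alphabetically first code
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety)), ]
  at <- at[order(at$eleno), ]

  at <- at[!(at$resid %in% WATER_CODES), , drop = FALSE]
  is_poly <- at$type == "ATOM" | at$resid %in% names(AA_PARENT)

  chains <- list()
  for (ch in sort(unique(at$chain[is_poly]))) {
    sub <- at[is_poly & at$chain == ch, , drop = FALSE]
    grp <- split(seq_len(nrow(sub)),
                 factor(paste(sub$resno, sub$insert), levels = unique(paste(sub$resno, sub$insert))))
    residues <- lapply(grp, function(idx) {
      r <- sub[idx, , drop = FALSE]
      new_residue(r$resno[1], r$resid[1],
                  atom_table(trimws(r$elety), r$elesy, r$x, r$y, r$z),
                  icode = r$insert[1], is_polymer = TRUE)
    })
    chains[[ch]] <- structure_chain(structure_id, ch, unname(residues))
  }
  if (length(chains) == 0) {
    warning("no polymer residues found in ", path)
    return(structure(list(), dropped_ligands = character(0)))
  }

  poly_xyz <- lapply(chains, chain_polymer_xyz)
  dropped <- character(0)
  het <- at[!is_poly, , drop = FALSE]
  if (nrow(het) > 0) {
    hgrp <- split(seq_len(nrow(het)),
                  paste(het$chain, het$resno, het$insert, het$resid))
    for (idx in hgrp) {
      h <- het[idx, , drop = FALSE]
      atoms <- atom_table(trimws(h$elety), h$elesy, h$x, h$y, h$z)
      lxyz <- atom_xyz(atoms)
      ncontact <- vapply(poly_xyz, function(pxyz) {
        if (nrow(pxyz) == 0) return(0L)
        d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
          2 * pxyz %*% t(lxyz)
        sum(rowSums(d2 <= ligand_contact_cutoff^2 + 1e-9) > 0)
      }, 0L)
      if (all(ncontact == 0)) {
        dropped <- c(dropped, h$resid[1])
        message(sprintf("ligand %s %d (chain %s) has no chain contact within %.1f A; dropped",
                        h$resid[1], h$resno[1], h$chain[1],
                        ligand_contact_cutoff))
        next
      }
      best <- names(chains)[which.max(ncontact)]  # ties: first = lower ID
      lig <- new_ligand(h$resid[1], atoms, number = h$resno[1],
                        chain_id = h$chain[1])
      chains[[best]]$ligands <- c(chains[[best]]$ligands, list(lig))
    }
  }
  structure(chains, dropped_ligands = dropped)
}

# ---------------------------------------------------------------------------
# Writing

format_pdb_atom <- function(record, serial, name, element, resname, chain,
                            resno, icode, x, y, z) {
  nm <- if (nchar(name) >= 4 || nchar(element) == 2) sprintf("%-4s", name)
        else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, nm, "", resname, chain, resno, icode,
          x, y, z, 1, 0, element)
}

#' Write structure chains to a PDB-format file
#'
#' Coordinates are written at PDB precision (3 decimals); ligand records keep
#' their original chain identifiers and residue numbers.
#'
#' @param chains a single \code{\link{structure_chain}} or a list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(chains, path) {
  if (inherits(chains, "aars_chain")) chains <- list(chains)
  out <- character(0)
  serial <- 0L
  for (chain in chains) {
    for (r in chain$residues) {
      for (i in seq_len(nrow(r$atoms))) {
        serial <- serial + 1L
        out <- c(out, format_pdb_atom("ATOM", serial, r$atoms$name[i],
                                      r$atoms$element[i], r$name,
                                      chain$chain_id, r$number, r$icode,
                                      r$atoms$x[i], r$atoms$y[i], r$atoms$z[i]))
      }
    }
    serial <- serial + 1L
    out <- c(out, "TER")
  }
  for (chain in chains) {
    for (lig in chain$ligands) {
      for (i in seq_len(nrow(lig$atoms))) {
        serial <- serial + 1L
        out <- c(out, format_pdb_atom("HETATM", serial, lig$atoms$name[i],
                                      lig$atoms$element[i],
                                      lig$component_code, lig$chain_id,
                                      lig$number, "",
                                      lig$atoms$x[i], lig$atoms$y[i],
                                      lig$atoms$z[i]))
      }
    }
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sequence

#' One-letter sequence of a chain's polymer residues
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param nonstandard \code{"strict"} maps nonstandard residues to "X";
#'   \code{"parent"} maps common modified residues (e.g. MSE) to their parent
#'   standard residue first.
#' @return single character string.
#' @export
chain_sequence <- function(chain, nonstandard = c("strict", "parent")) {
  nonstandard <- match.arg(nonstandard)
  res <- polymer_residues(chain)
  if (length(res) == 0) stop("chain has no polymer residues")
  letters1 <- vapply(res, function(r) {
    nm <- r$name
    if (nonstandard == "parent" && nm %in% names(AA_PARENT))
      nm <- AA_PARENT[[nm]]
    AA_THREE_TO_ONE[nm] %||% NA_character_
  }, "")
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# ---------------------------------------------------------------------------
# Bond inference and ring perception

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded if their distance is below the sum of their covalent
#' radii plus \code{slack} Angstrom (common heuristic for HET groups lacking
#' connectivity records).
#'
#' @param atoms an \code{\link{atom_table}}.
#' @param slack distance slack in Angstrom.
#' @return two-column integer matrix of bonded atom index pairs.
#' @export
infer_bonds <- function(atoms, slack = 0.4) {
  n <- nrow(atoms)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  xyz <- atom_xyz(atoms)
  d <- as.matrix(stats::dist(xyz))
  r <- COVALENT_RADII[atoms$element]
  r[is.na(r)] <- 0.77
  thresh <- outer(r, r, "+") + slack
  hit <- which(d < thresh & d > 0.4 & upper.tri(d), arr.ind = TRUE)
  unname(hit)
}

# All simple rings of size <= max_size: for each edge, the shortest
# alternative path between its endpoints closes a ring.
find_rings <- function(bonds, n_atoms, max_size = 6) {
  if (nrow(bonds) == 0) return(list())
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  rings <- list()
  for (i in seq_len(nrow(bonds))) {
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, bonds[i, ]))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = bonds[i, 1], to = bonds[i, 2]))
    vp <- sp$vpath[[1]]
    if (length(vp) >= 2 && length(vp) <= max_size)
      rings[[length(rings) + 1]] <- sort(as.integer(vp))
  }
  unique(rings)
}

# ---------------------------------------------------------------------------
# Ligand moiety classification

.ligand_component_env <- new.env(parent = emptyenv())

ligand_component_table <- function() {
  if (is.null(.ligand_component_env$tab)) {
    path <- system.file("extdata", "ligand_components.json",
                        package = "aarsmotifs")
    .ligand_component_env$tab <- jsonlite::fromJSON(path)
  }
  .ligand_component_env$tab
}

# Moiety sets detected on the bond graph: adenine-like fused 6-5 aromatic
# N-heterocycle, ribose-like 5-ring with one ring oxygen, phosphate groups.
ligand_moieties <- function(atoms, bonds = infer_bonds(atoms)) {
  n <- nrow(atoms)
  rings <- find_rings(bonds, n)
  sizes <- lengths(rings)
  elem <- atoms$element
  neighbors <- lapply(seq_len(n), function(i)
    c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1]))

  adenine <- integer(0)
  for (i in which(sizes == 6)) for (j in which(sizes == 5)) {
    shared <- intersect(rings[[i]], rings[[j]])
    fused <- union(rings[[i]], rings[[j]])
    if (length(shared) >= 2 && all(elem[fused] %in% c("C", "N")) &&
        sum(elem[fused] == "N") >= 4) {
      adenine <- union(adenine, fused)
    }
  }
  ribose <- integer(0)
  for (j in which(sizes == 5)) {
    rg <- rings[[j]]
    if (sum(elem[rg] == "O") == 1 && sum(elem[rg] == "C") == 4 &&
        !any(rg %in% adenine)) {
      ribose <- union(ribose, rg)
    }
  }
  phosphate <- integer(0)
  for (p in which(elem == "P")) {
    ox <- intersect(neighbors[[p]], which(elem == "O"))
    if (length(ox) >= 3) phosphate <- union(phosphate, c(p, ox))
  }
  list(adenine = adenine, ribose = ribose, phosphate = phosphate,
       bonds = bonds, neighbors = neighbors, rings = rings)
}

#' Classify a ligand's moieties
#'
#' A ligand carries an adenosine-phosphate moiety if its component code is on
#' the packaged curated list, or if its bond graph contains a fused 6-5
#' aromatic N-heterocycle (>= 4 nitrogens) attached to a five-ring with a
#' ring oxygen plus an exocyclic phosphate group. It carries an amino-acid
#' part if the code is a standard amino acid or a free alpha-amino-acid
#' fragment (N-CA-carboxyl/carbonyl) exists outside the nucleotide fragment.
#' An aminoacyl adenylate therefore sets both flags.
#'
#' @param component_code chemical component ID.
#' @param atoms an \code{\link{atom_table}} (may be NULL for code-only
#'   classification).
#' @return list with logical \code{has_adenosine_phosphate} and
#'   \code{has_amino_acid_part}.
#' @export
classify_ligand <- function(component_code, atoms = NULL) {
  tab <- ligand_component_table()
  code <- toupper(component_code)
  ap <- code %in% tab$adenosine_phosphate || code %in% tab$aminoacyl_adenylate
  aa <- code %in% tab$amino_acid || code %in% tab$aminoacyl_adenylate

  if (!is.null(atoms) && nrow(atoms) >= 3) {
    m <- ligand_moieties(atoms)
    nucleotide <- unique(c(m$adenine, m$ribose, m$phosphate))
    if (length(m$adenine) && length(m$ribose) && length(m$phosphate)) {
      rib_adj <- any(vapply(m$ribose, function(i)
        any(m$neighbors[[i]] %in% m$adenine), TRUE))
      p_near <- any(vapply(m$phosphate[atoms$element[m$phosphate] == "P"],
        function(p) {
          g <- igraph::graph_from_edgelist(m$bonds, directed = FALSE)
          if (igraph::vcount(g) < nrow(atoms))
            g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
          dd <- igraph::distances(g, v = p, to = m$ribose)
          any(is.finite(dd) & dd <= 4)
        }, TRUE))
      if (rib_adj && p_near) ap <- TRUE
    }
    # free alpha-amino-acid fragment outside the nucleotide atoms
    elem <- atoms$element
    for (nn in which(elem == "N")) {
      if (nn %in% nucleotide) next
      for (ca in intersect(m$neighbors[[nn]], which(elem == "C"))) {
        if (ca %in% nucleotide) next
        for (cc in setdiff(intersect(m$neighbors[[ca]], which(elem == "C")), ca)) {
          if (cc %in% nucleotide) next
          ox <- intersect(m$neighbors[[cc]], which(elem == "O"))
          ox <- setdiff(ox, m$phosphate)
          if (length(ox) >= 1) aa <- TRUE
        }
      }
    }
  }
  if (!ap && !aa)
    message("ligand component '", code, "' matched no known moiety")
  list(has_adenosine_phosphate = ap, has_amino_acid_part = aa)
}
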