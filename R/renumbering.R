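# MSA-guided residue renumbering: every chain's author residue numbers are
# mapped onto the unified 1-based column positions of a class-specific
# (structure-guided) multiple sequence alignment.

#' Read a gapped protein MSA from FASTA
#'
#' @param path FASTA file; gap character "-".
#' @return list with \code{rows} (named character vector of gapped
#'   sequences) and \code{width} (alignment length).
#' @export
read_msa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  rows <- as.character(ss)
  names(rows) <- sub("\\s.*$", "", names(ss))
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("MSA rows differ in length")
  list(rows = rows, width = w)
}

ungap <- function(s) gsub("-", "", s)

#' Choose the MSA row matching a chain sequence
#'
#' The row maximizing global identity to the chain sequence is selected. If a
#' row name equal to \code{row_hint} exists it is tried first and accepted at
#' or above the refusal threshold without scanning the rest (the alignment
#' used for renumbering is typically built from the very structures being
#' renumbered). Mapping is refused if the best identity is below
#' \code{min_identity} percent.
#'
#' @param chain_seq one-letter chain sequence (length >= 30).
#' @param msa result of \code{\link{read_msa}}.
#' @param min_identity refusal threshold, percent.
#' @param row_hint optional row name to try first.
#' @return list with \code{row_id}, \code{identity}, \code{alignment}
#'   (gapped chain/row strings) or, on refusal, \code{failed = TRUE} with the
#'   best identity found.
#' @export
map_chain_to_row <- function(chain_seq, msa, min_identity = 40,
                             row_hint = NULL) {
  stopifnot(nchar(chain_seq) >= 30)
  try_row <- function(id) {
    al <- nw_align(chain_seq, ungap(msa$rows[[id]]))
    list(row_id = id, alignment = al,
         identity = identity_from_alignment(al$pattern, al$subject))
  }
  if (!is.null(row_hint) && row_hint %in% names(msa$rows)) {
    cand <- try_row(row_hint)
    if (cand$identity >= min_identity) return(c(cand, failed = FALSE))
  }
  ids <- global_identity_many(vapply(msa$rows, ungap, ""), chain_seq)
  best_id <- names(msa$rows)[which.max(ids)]
  if (max(ids) < min_identity) {
    return(list(row_id = best_id, identity = max(ids), failed = TRUE))
  }
  c(try_row(best_id), failed = FALSE)
}

# Column index in the gapped row for each ungapped row position.
row_position_to_column <- function(gapped_row) {
  which(strsplit(gapped_row, "")[[1]] != "-")
}

#' Build the author-number to MSA-column map for a chain
#'
#' Composes the chain-to-row pairwise alignment with the row's gap pattern:
#' chain residue i aligned to ungapped row position j is assigned the MSA
#' column holding j. Unaligned chain residues and unused columns are
#' reported. The resulting map is injective and strictly increasing along
#' the chain.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param msa result of \code{\link{read_msa}}.
#' @param min_identity refusal threshold (percent) for the row match.
#' @param row_hint optional row name tried first (see
#'   \code{\link{map_chain_to_row}}).
#' @return list of class \code{aars_renumber_map}: \code{entries}
#'   (data.frame author_number, icode, msa_column), \code{unmapped_author},
#'   \code{unmapped_columns}, \code{row_id}, \code{identity}; or a failure
#'   record with \code{failed = TRUE}.
#' @export
build_renumber_map <- function(chain, msa, min_identity = 40,
                               row_hint = NULL) {
  chain_seq <- chain_sequence(chain, nonstandard = "parent")
  m <- map_chain_to_row(chain_seq, msa, min_identity,
                        row_hint = row_hint %||% chain$structure_id)
  res <- polymer_residues(chain)
  author <- data.frame(author_number = vapply(res, function(r) r$number, 1L),
                       icode = vapply(res, function(r) r$icode, ""))
  if (isTRUE(m$failed)) {
    return(structure(list(failed = TRUE, row_id = m$row_id,
                          identity = m$identity,
                          structure_id = chain$structure_id,
                          chain_id = chain$chain_id),
                     class = "aars_renumber_map"))
  }
  pa <- strsplit(m$alignment$pattern, "")[[1]]
  sa <- strsplit(m$alignment$subject, "")[[1]]
  col_of_rowpos <- row_position_to_column(msa$rows[[m$row_id]])
  ci <- 0L; rj <- 0L
  chain_col <- rep(NA_integer_, nchar(chain_seq))
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ci <- ci + 1L
    if (sa[k] != "-") rj <- rj + 1L
    if (pa[k] != "-" && sa[k] != "-") chain_col[ci] <- col_of_rowpos[rj]
  }
  entries <- cbind(author[!is.na(chain_col), , drop = FALSE],
                   msa_column = chain_col[!is.na(chain_col)])
  structure(list(failed = FALSE, row_id = m$row_id, identity = m$identity,
                 structure_id = chain$structure_id,
                 chain_id = chain$chain_id, entries = entries,
                 unmapped_author = author[is.na(chain_col), , drop = FALSE],
                 unmapped_columns = setdiff(seq_len(msa$width),
                                            entries$msa_column)),
            class = "aars_renumber_map")
}

#' Renumber a chain's polymer residues to MSA columns
#'
#' Mapped polymer residues receive their MSA column as residue number;
#' unmapped polymer residues keep their author number negated (so they
#' cannot collide with 1-based columns and remain writable as PDB). Ligand
#' records are left untouched. \code{\link{strip_renumbering}} inverts the
#' operation.
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param map an \code{aars_renumber_map} from
#'   \code{\link{build_renumber_map}}.
#' @return the renumbered chain, with attribute \code{"renumber_map"}.
#' @export
renumber_chain <- function(chain, map) {
  if (isTRUE(map$failed)) stop("cannot renumber: mapping failed for ",
                               chain$structure_id, ":", chain$chain_id)
  stopifnot(nrow(map$entries) >= 1)
  keymap <- stats::setNames(map$entries$msa_column,
                            paste(map$entries$author_number,
                                  map$entries$icode))
  chain$residues <- lapply(chain$residues, function(r) {
    if (!r$is_polymer) return(r)
    col <- keymap[paste(r$number, r$icode)]
    if (!is.na(col)) { r$number <- as.integer(col); r$icode <- "" }
    else r$number <- -abs(r$number)
    r
  })
  attr(chain, "renumber_map") <- map
  chain
}

#' Undo renumbering
#'
#' @param chain a renumbered chain carrying its \code{"renumber_map"}
#'   attribute.
#' @return the chain with original author numbering restored.
#' @export
strip_renumbering <- function(chain) {
  map <- attr(chain, "renumber_map")
  if (is.null(map)) stop("chain carries no renumber_map attribute")
  inv <- stats::setNames(paste(map$entries$author_number, map$entries$icode,
                               sep = "\r"),
                         map$entries$msa_column)
  chain$residues <- lapply(chain$residues, function(r) {
    if (!r$is_polymer) return(r)
    if (r$number < 0) { r$number <- -r$number; return(r) }
    orig <- inv[as.character(r$number)]
    if (!is.na(orig)) {
      parts <- strsplit(orig, "\r")[[1]]
      r$number <- as.integer(parts[1])
      r$icode <- if (length(parts) > 1) parts[2] else ""
    }
    r
  })
  attr(chain, "renumber_map") <- NULL
  chain
}

# ---------------------------------------------------------------------------
# Motif definitions and urzyme regions

#' Motif definitions at unified alignment positions
#'
#' The Class I Backbone Brackets sit at renumbered positions 274 and 1361
#' (adenosine phosphate bound via backbone hydrogen bonds); the Class II
#' Arginine Tweezers are the invariant arginines at positions 698 and 1786
#' (salt bridges / pi-cation contacts). Position 700, the conserved glutamate
#' contacting the adenine in several Class II types, is carried as an
#' auxiliary position of interest.
#'
#' @return named list of motif definitions.
#' @export
motif_definitions <- function() {
  list(
    BackboneBrackets = list(name = "Backbone Brackets", aars_class = "I",
                            positions = c(274L, 1361L),
                            auxiliary = integer(0)),
    ArginineTweezers = list(name = "Arginine Tweezers", aars_class = "II",
                            positions = c(698L, 1786L), auxiliary = 700L)
  )
}

#' Catalog of ancestral coding regions at renumbered positions
#'
#' Intervals of unified alignment positions corresponding to the proposed
#' complementary-coding regions: the "HIGH-Motif 2" (protozyme) region and
#' the "KMSKS-Motif 1" region, per class.
#'
#' @return data.frame with columns class, region, start, end.
#' @export
region_catalog <- function() {
  data.frame(
    class = c("I", "II", "I", "II"),
    region = c("HIGH-Motif2", "HIGH-Motif2", "KMSKS-Motif1", "KMSKS-Motif1"),
    start = c(255L, 648L, 1352L, 347L),
    end = c(336L, 718L, 1452L, 371L),
    stringsAsFactors = FALSE
  )
}

#' Locate a motif in a renumbered chain
#'
#' @param chain a renumbered \code{\link{structure_chain}}.
#' @param motif one element of \code{\link{motif_definitions}}.
#' @return list with \code{found} (logical), \code{residues} (list of the two
#'   residues when found) and \code{missing} (the unmapped position numbers
#'   otherwise). Both residues must expose a CA atom.
#' @export
locate_motif <- function(chain, motif) {
  res <- polymer_residues(chain)
  num <- vapply(res, function(r) r$number, 1L)
  picked <- lapply(motif$positions, function(p) {
    i <- which(num == p)
    if (length(i) != 1) return(NULL)
    r <- res[[i]]
    if (is.null(residue_atom(r, "CA"))) return(NULL)
    r
  })
  missing <- motif$positions[vapply(picked, is.null, TRUE)]
  if (length(missing)) list(found = FALSE, residues = NULL, missing = missing)
  else list(found = TRUE, residues = picked, missing = integer(0))
}

#' Write renumbering maps as a TSV mapping table
#'
#' One row per mapped residue: pdb_id, chain, author_number, icode,
#' msa_column.
#'
#' @param maps list of \code{aars_renumber_map} objects.
#' @param path output TSV path.
#' @return the combined data.frame, invisibly.
#' @export
write_mapping_table <- function(maps, path) {
  ok <- Filter(function(m) !isTRUE(m$failed), maps)
  df <- do.call(rbind, lapply(ok, function(m)
    cbind(pdb_id = m$structure_id, chain = m$chain_id, m$entries)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write the list of structures whose mapping failed
#'
#' @param maps list of \code{aars_renumber_map} objects.
#' @param path output text path (one "pdb_id chain identity" row per failure).
#' @return character vector of failed ids, invisibly.
#' @export
write_failure_list <- function(maps, path) {
  bad <- Filter(function(m) isTRUE(m$failed), maps)
  lines <- vapply(bad, function(m)
    sprintf("%s %s best_identity=%.1f", m$structure_id, m$chain_id,
            m$identity), "")
  writeLines(lines, path)
  invisible(lines)
}
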