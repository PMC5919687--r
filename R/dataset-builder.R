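# Dataset assembly: chain annotations, M1/M2 binding-mode assignment,
# sequence-identity clustering and representative selection.

# Class membership of the aaRS types (lysyl-tRNA synthetases occur in both
# classes and are annotated per chain in the input table).
AARS_CLASS_TYPES <- list(
  I  = c("ArgRS", "CysRS", "GluRS", "GlnRS", "IleRS", "LeuRS", "LysRS-I",
         "MetRS", "TrpRS", "TyrRS", "ValRS"),
  II = c("AlaRS", "AsnRS", "AspRS", "GlyRS", "HisRS", "LysRS-II", "PheRS",
         "ProRS", "SerRS", "ThrRS", "PylRS", "SepRS")
)

#' Assign the adenosine-phosphate binding mode of a chain
#'
#' M1 is the state with an adenosine-phosphate-containing ligand in the
#' active site; M2 covers apo chains and chains whose ligands bind only the
#' aminoacyl part.
#'
#' @param chain a \code{\link{structure_chain}} with classified ligands.
#' @return \code{"M1"} or \code{"M2"}.
#' @export
assign_binding_mode <- function(chain) {
  ap <- vapply(chain$ligands, function(l) isTRUE(l$has_adenosine_phosphate),
               TRUE)
  if (length(ap) && any(ap)) "M1" else "M2"
}

#' Global sequence identity (Needleman-Wunsch)
#'
#' Aligns the two sequences globally with BLOSUM62 and affine gap costs
#' (open 10, extend 0.5) and reports percent identity over aligned columns,
#' excluding terminal-gap overhangs from the denominator so that constructs
#' differing only in tails (expression tags, unresolved termini) are not
#' penalized.
#'
#' @param seq_a,seq_b amino-acid strings.
#' @param gap_opening,gap_extension affine gap parameters.
#' @return percent identity in \code{[0, 100]}.
#' @export
global_identity <- function(seq_a, seq_b, gap_opening = 10,
                            gap_extension = 0.5) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  global_identity_many(seq_a, seq_b, gap_opening, gap_extension)
}

# vectorized percent identity of many patterns against one subject; the
# aligned region of a Biostrings global alignment is exactly the
# terminal-overhang-free column range, so identity = nmatch / region width
global_identity_many <- function(patterns, subject, gap_opening = 10,
                                 gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
  w <- Biostrings::nchar(pa)
  ifelse(w > 0, 100 * Biostrings::nmatch(pa) / w, 0)
}

# Global NW alignment via Biostrings; returns the two gapped strings.
nw_align <- function(seq_a, seq_b, gap_opening = 10, gap_extension = 0.5) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = gap_opening, gapExtension = gap_extension, type = "global")
  list(pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

.blosum_env <- new.env(parent = emptyenv())
blosum62_matrix <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62
  }
  .blosum_env$m
}

# Percent identity of an aligned pair, terminal-gap overhang columns excluded.
identity_from_alignment <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  notgap_a <- which(ca != "-")
  notgap_b <- which(cb != "-")
  lo <- max(min(notgap_a), min(notgap_b))
  hi <- min(max(notgap_a), max(notgap_b))
  if (hi < lo) return(0)
  idx <- lo:hi
  100 * sum(ca[idx] == cb[idx] & ca[idx] != "-") / length(idx)
}

#' Single-linkage sequence-identity clustering
#'
#' Chains are clustered as the connected components of the graph whose edges
#' join pairs with global identity above the threshold (single linkage, i.e.
#' chaining is allowed).
#'
#' @param sequences named character vector of chain sequences.
#' @param identity_threshold percent identity; an edge requires identity
#'   strictly above it (default 95).
#' @param identities optional precomputed symmetric identity matrix.
#' @return list of character vectors of sequence names (clusters), ordered by
#'   first occurrence.
#' @export
single_linkage_clusters <- function(sequences, identity_threshold = 95,
                                    identities = NULL) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100)
  n <- length(sequences)
  ids <- names(sequences) %||% as.character(seq_len(n))
  if (n == 0) return(list())
  if (is.null(identities)) {
    identities <- matrix(0, n, n)
    if (n > 1) {
      for (j in 2:n) {
        idj <- global_identity_many(unlist(sequences[1:(j - 1)]),
                                    sequences[[j]])
        identities[1:(j - 1), j] <- identities[j, 1:(j - 1)] <- idj
      }
    }
  }
  edges <- which(identities > identity_threshold & upper.tri(identities),
                 arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  split(ids, comp)[unique(comp)]
}

#' Select a cluster representative
#'
#' Deterministic priority: wild type over mutant, then (for the M1 or M2
#' representative) a binding-mode match, then best (lowest) resolution, then
#' the lexicographically smallest (structure_id, chain_id).
#'
#' @param annotations data.frame with columns \code{pdb_id}, \code{chain},
#'   \code{mutant} (logical), \code{resolution} (Angstrom, NA allowed) and
#'   \code{binding_mode} ("M1"/"M2"), one row per cluster member.
#' @param mode \code{"overall"}, \code{"M1"} or \code{"M2"}.
#' @param priority character vector ordering the criteria; reorder to change
#'   the scheme.
#' @return the selected row of \code{annotations}.
#' @export
select_representative <- function(annotations, mode = c("overall", "M1", "M2"),
                                  priority = c("wildtype", "mode",
                                               "resolution", "id")) {
  mode <- match.arg(mode)
  stopifnot(nrow(annotations) >= 1)
  keys <- list(
    wildtype = as.integer(isTRUE_vec(annotations$mutant)),       # FALSE first
    mode = if (mode == "overall") rep(0L, nrow(annotations))
           else as.integer(annotations$binding_mode != mode),    # match first
    resolution = ifelse(is.na(annotations$resolution), Inf,
                        annotations$resolution),
    id = paste(annotations$pdb_id, annotations$chain)
  )
  ord <- do.call(order, unname(keys[priority]))
  annotations[ord[1], , drop = FALSE]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Read a chain annotation table
#'
#' Tab-separated table with columns \code{pdb_id}, \code{chain},
#' \code{class} (I/II), \code{type}, \code{superkingdom}, \code{taxid},
#' \code{mutant}, \code{resolution} and optionally \code{ligands} (comma
#' separated component codes) and \code{binding_mode}. Class/type consistency
#' is checked against the packaged class partition.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pdb_id = "character",
                                         chain = "character"))
  need <- c("pdb_id", "chain", "class", "type", "superkingdom", "taxid",
            "mutant", "resolution")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table lacks columns: ",
                         paste(miss, collapse = ", "))
  df$mutant <- as.logical(df$mutant)
  bad <- !mapply(function(cl, ty) ty %in% (AARS_CLASS_TYPES[[cl]] %||% character(0)),
                 df$class, df$type)
  if (any(bad))
    stop("class/type inconsistency for: ",
         paste(df$pdb_id[bad], df$type[bad], collapse = "; "))
  df
}

#' Assemble the annotated, clustered dataset
#'
#' Computes binding modes from the parsed chains, clusters the sequences at
#' the identity threshold, and marks the overall, M1 and M2 representative of
#' every cluster.
#'
#' @param chains named list of \code{\link{structure_chain}} objects; names
#'   are "pdbid_chain" keys matching the annotation rows.
#' @param annotations annotation data.frame (see
#'   \code{\link{read_annotation_table}}).
#' @param identity_threshold clustering threshold (percent).
#' @return \code{annotations} with added columns \code{binding_mode},
#'   \code{cluster}, \code{representative}, \code{representative_m1},
#'   \code{representative_m2}.
#' @export
build_dataset <- function(chains, annotations, identity_threshold = 95) {
  key <- paste(annotations$pdb_id, annotations$chain, sep = "_")
  if (!all(key %in% names(chains)))
    stop("chains missing for: ",
         paste(setdiff(key, names(chains)), collapse = ", "))
  chains <- chains[key]
  annotations$binding_mode <-
    vapply(chains, assign_binding_mode, "")
  seqs <- vapply(chains, chain_sequence, "")
  names(seqs) <- key
  cl <- single_linkage_clusters(seqs, identity_threshold)
  annotations$cluster <- NA_integer_
  for (i in seq_along(cl)) annotations$cluster[key %in% cl[[i]]] <- i
  annotations$representative <- FALSE
  annotations$representative_m1 <- FALSE
  annotations$representative_m2 <- FALSE
  for (i in seq_along(cl)) {
    rows <- which(annotations$cluster == i)
    sub <- annotations[rows, , drop = FALSE]
    pick <- function(mode) {
      r <- select_representative(sub, mode)
      rows[which(paste(sub$pdb_id, sub$chain) ==
                   paste(r$pdb_id, r$chain))[1]]
    }
    annotations$representative[pick("overall")] <- TRUE
    if (any(sub$binding_mode == "M1"))
      annotations$representative_m1[pick("M1")] <- TRUE
    if (any(sub$binding_mode == "M2"))
      annotations$representative_m2[pick("M2")] <- TRUE
  }
  annotations
}

#' Write the dataset table as TSV and JSON
#'
#' @param dataset data.frame from \code{\link{build_dataset}}.
#' @param tsv,json output paths (either may be NULL to skip).
#' @return invisibly, the dataset.
#' @export
write_dataset <- function(dataset, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(dataset, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(dataset, json, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(dataset)
}
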