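# Codon assignment to renumbered positions, information-thresholded
# consensus codons, and antisense (complementary-strand) middle-base pairing
# between the Class I and Class II ancestral coding regions.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Assign codons of a coding sequence to MSA columns
#'
#' The coding sequence must translate (standard code, terminal stop allowed)
#' to the ungapped protein row; residue i then receives codon
#' \code{cds[3i-2 .. 3i]}, attached to that residue's MSA column.
#'
#' @param protein ungapped protein sequence of the MSA row.
#' @param cds coding DNA string (A/C/G/T).
#' @param column_map integer vector: MSA column of each protein position
#'   (as from \code{row_position_to_column} on the gapped row).
#' @return data.frame (msa_column, codon).
#' @export
assign_codons <- function(protein, cds, column_map) {
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3 != 0)
    stop("coding sequence length is not a multiple of 3")
  n <- nchar(protein)
  ncod <- nchar(cds) / 3
  if (!(ncod == n || ncod == n + 1))
    stop(sprintf("coding sequence (%d codons) does not match protein length (%d)",
                 ncod, n))
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (ncod == n + 1) {
    if (substr(tr, ncod, ncod) != "*")
      stop("trailing codon is not a stop codon")
    tr <- substr(tr, 1, n)
  }
  if (tr != protein)
    stop("coding sequence does not translate to the protein row")
  if (length(column_map) != n)
    stop("column map length does not match protein length")
  codons <- substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  data.frame(msa_column = column_map, codon = codons,
             stringsAsFactors = FALSE)
}

#' Collect per-column codon observations across a cohort
#'
#' @param assignments list of data.frames from \code{\link{assign_codons}}.
#' @return named list: for each MSA column (name = column number) the
#'   character vector of contributed codons.
#' @export
codon_columns <- function(assignments) {
  all <- do.call(rbind, assignments)
  split(all$codon, all$msa_column)
}

base_information <- function(bases) {
  freq <- table(factor(bases, levels = c("A", "C", "G", "T")))
  p <- freq / sum(freq)
  p <- p[p > 0]
  2 + sum(p * log2(p))  # information content = 2 - Shannon entropy (bits)
}

#' Consensus codon of one MSA column
#'
#' Per base position, the information content over the contributing codons is
#' 2 - H (Shannon entropy, log2, 4-letter alphabet). The modal base is
#' assigned where the information content exceeds \code{threshold_bits};
#' other positions (including modal ties) get 'x'.
#'
#' @param codons character vector of 3-base codons observed at the column.
#' @param threshold_bits information threshold in bits (default 1).
#' @return list with \code{bases} (3-character string over A/C/G/T/x),
#'   \code{information} (numeric length 3) and \code{occupancy}.
#' @export
consensus_codon <- function(codons, threshold_bits = 1.0) {
  stopifnot(length(codons) >= 1)
  codons <- toupper(codons)
  stopifnot(all(grepl("^[ACGT]{3}$", codons)))
  bases <- character(3)
  info <- numeric(3)
  for (k in 1:3) {
    bk <- substr(codons, k, k)
    info[k] <- base_information(bk)
    tab <- sort(table(bk), decreasing = TRUE)
    modal_tie <- length(tab) > 1 && tab[1] == tab[2]
    bases[k] <- if (info[k] > threshold_bits && !modal_tie) names(tab)[1]
                else "x"
  }
  list(bases = paste(bases, collapse = ""), information = info,
       occupancy = length(codons))
}

#' Consensus codons for a set of columns
#'
#' @param columns list from \code{\link{codon_columns}} (names are MSA
#'   columns).
#' @param threshold_bits information threshold in bits.
#' @param min_occupancy columns with fewer contributing codons are dropped
#'   (low-occupancy omission; set 0 to keep everything).
#' @return data.frame (msa_column, consensus, occupancy, info1..info3).
#' @export
consensus_codons <- function(columns, threshold_bits = 1.0,
                             min_occupancy = 0) {
  keep <- names(columns)[lengths(columns) >= min_occupancy]
  rows <- lapply(keep, function(cn) {
    cc <- consensus_codon(columns[[cn]], threshold_bits)
    data.frame(msa_column = as.integer(cn), consensus = cc$bases,
               occupancy = cc$occupancy, info1 = cc$information[1],
               info2 = cc$information[2], info3 = cc$information[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$msa_column), ]
}

#' Antisense codon pairing between the two classes
#'
#' The two consensus lists are taken as already column-aligned (row i of
#' Class I pairs with row i of Class II, the Class II region read in the
#' antiparallel direction). Class II codons stored 5'->3' are reversed at
#' pairing time so that base 1 of a Class I codon faces base 3 of its Class
#' II partner and middle faces middle; codons taken from a printed pairing
#' layout are already in that orientation
#' (\code{classII_reversed = TRUE}). A base pair is a \code{match} iff both
#' bases are assigned and Watson-Crick complementary (A-T / G-C, no wobble);
#' \code{mismatch} if both assigned and not complementary; \code{unassigned}
#' otherwise.
#'
#' @param classI,classII data.frames with columns \code{msa_column} and
#'   \code{consensus} (3 characters over A/C/G/T/x), equal row counts,
#'   aligned pairing order.
#' @param classII_reversed are the Class II codons already written in
#'   pairing (reversed) orientation?
#' @return list of class \code{aars_pairing}: \code{pairs} data.frame
#'   (classI_column, classII_column, classI_codon, classII_codon_paired,
#'   verdict1..verdict3, marker), \code{middle_base_matches},
#'   \code{match_positions} (classI columns of middle matches).
#' @export
antisense_pairing <- function(classI, classII, classII_reversed = FALSE) {
  if (nrow(classI) != nrow(classII))
    stop("pairing requires equally many aligned columns on both strands")
  revstr <- function(s) vapply(s, function(x)
    paste(rev(strsplit(x, "")[[1]]), collapse = ""), "")
  cII <- classII$consensus
  if (!classII_reversed) cII <- revstr(cII)
  verdicts <- matrix("", nrow(classI), 3)
  for (i in seq_len(nrow(classI))) {
    a <- strsplit(classI$consensus[i], "")[[1]]
    b <- strsplit(cII[i], "")[[1]]
    for (k in 1:3) {
      verdicts[i, k] <-
        if (a[k] == "x" || b[k] == "x") "unassigned"
        else if (DNA_COMPLEMENT[[a[k]]] == b[k]) "match"
        else "mismatch"
    }
  }
  marker <- apply(verdicts, 1, function(v)
    paste(vapply(v, function(x) switch(x, match = "|", mismatch = "x",
                                       unassigned = "."), ""),
          collapse = ""))
  pairs <- data.frame(classI_column = classI$msa_column,
                      classII_column = classII$msa_column,
                      classI_codon = classI$consensus,
                      classII_codon_paired = cII,
                      verdict1 = verdicts[, 1], verdict2 = verdicts[, 2],
                      verdict3 = verdicts[, 3], marker = marker,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 middle_base_matches = sum(verdicts[, 2] == "match"),
                 match_positions =
                   classI$msa_column[verdicts[, 2] == "match"]),
            class = "aars_pairing")
}

#' @export
print.aars_pairing <- function(x, ...) {
  cat(format_pairing_table(x), sep = "\n")
  invisible(x)
}

#' Plain-text pairing table
#'
#' Layout mirroring the published codon-assignment tables: a Class I codon
#' row, a marker row ('.' unassigned, '|' match, 'x' mismatch) and the
#' Class II codon row in pairing orientation.
#'
#' @param pairing result of \code{\link{antisense_pairing}}.
#' @return character vector of lines.
#' @export
format_pairing_table <- function(pairing) {
  p <- pairing$pairs
  c(paste(c("C I ", sprintf("%5d", p$classI_column)), collapse = ""),
    paste(c("     ", sprintf("%5s", p$classI_codon)), collapse = ""),
    paste(c("     ", sprintf("%5s", p$marker)), collapse = ""),
    paste(c("C II ", sprintf("%5s", p$classII_codon_paired)), collapse = ""),
    paste(c("     ", sprintf("%5d", p$classII_column)), collapse = ""))
}

#' Read a printed consensus-codon table fixture
#'
#' TSV with columns \code{classI_column}, \code{classI_codon},
#' \code{classII_codon}, \code{classII_column}; Class II codons are stored
#' exactly as printed in pairing orientation.
#'
#' @param path TSV path.
#' @return list with \code{classI} and \code{classII} data.frames suitable
#'   for \code{\link{antisense_pairing}} with \code{classII_reversed=TRUE}.
#' @export
read_consensus_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  list(classI = data.frame(msa_column = df$classI_column,
                           consensus = df$classI_codon,
                           stringsAsFactors = FALSE),
       classII = data.frame(msa_column = df$classII_column,
                            consensus = df$classII_codon,
                            stringsAsFactors = FALSE))
}
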