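#!/usr/bin/env Rscript
# Stage 6: antisense codon analysis. Codons are assigned to renumbered
# positions from the cohort coding sequences, consensus codons computed with
# the 1-bit information threshold, and the Class I / Class II ancestral
# coding windows paired antiparallel (middle base against middle base).
# The published consensus tables for the HIGH-Motif 2 and KMSKS-Motif 1
# regions are re-paired the same way.

source("analysis/00_common.R")

cons <- list()
for (cls in c("I", "II")) {
  require_stage(file.path(cohort_dir(cls), "cds.fasta"),
                "analysis/01_simulate.R")
  message("assigning Class ", cls, " codons ...")
  cc <- load_cohort_chains(cls)
  msa <- read_msa(file.path(cohort_dir(cls), "msa.fasta"))
  cds <- Biostrings::readDNAStringSet(file.path(cohort_dir(cls),
                                                "cds.fasta"))
  cdsv <- stats::setNames(as.character(cds), sub("\\s.*", "", names(cds)))
  assignments <- list()
  for (k in names(cc$chains)) {
    ch <- cc$chains[[k]]
    map <- build_renumber_map(ch, msa)
    if (isTRUE(map$failed)) next
    a <- assign_codons(chain_sequence(ch), cdsv[[ch$structure_id]],
                       map$entries$msa_column)
    assignments[[length(assignments) + 1]] <- a
  }
  cols <- codon_columns(assignments)
  cons[[cls]] <- consensus_codons(cols)
  write_result(cons[[cls]], sprintf("06_consensus_codons_class%d.tsv",
                                    match(cls, c("I", "II"))))
}

# synthetic designed windows, antiparallel
wI <- cons$I[cons$I$msa_column %in% 272:285, c("msa_column", "consensus")]
wII <- cons$II[cons$II$msa_column %in% 688:701, c("msa_column", "consensus")]
p_syn <- antisense_pairing(wI[order(wI$msa_column), ],
                           wII[order(-wII$msa_column), ])
cat("Synthetic HIGH-Motif 2 window pairing:\n")
print(p_syn)
cat(sprintf("synthetic middle-base matches: %d at Class I columns %s\n",
            p_syn$middle_base_matches,
            paste(p_syn$match_positions, collapse = ", ")))

# published consensus-codon tables
report_table <- function(file, label) {
  tab <- read_consensus_table(system.file("extdata", file,
                                          package = "aarsmotifs"))
  p <- antisense_pairing(tab$classI, tab$classII, classII_reversed = TRUE)
  cat("\n", label, "pairing:\n")
  print(p)
  cat(sprintf("%s middle-base matches: %d at Class I columns %s\n", label,
              p$middle_base_matches,
              paste(p$match_positions, collapse = ", ")))
  p
}
p_high <- report_table("high_motif2_consensus.tsv", "HIGH-Motif 2")
p_k <- report_table("kmsks_motif1_consensus.tsv", "KMSKS-Motif 1")
write_result(rbind(
  data.frame(region = "HIGH-Motif2", source = "published",
             middle_base_matches = p_high$middle_base_matches,
             match_columns = paste(p_high$match_positions, collapse = ",")),
  data.frame(region = "KMSKS-Motif1", source = "published",
             middle_base_matches = p_k$middle_base_matches,
             match_columns = paste(p_k$match_positions, collapse = ",")),
  data.frame(region = "HIGH-Motif2", source = "synthetic",
             middle_base_matches = p_syn$middle_base_matches,
             match_columns = paste(p_syn$match_positions, collapse = ","))),
  "06_middle_base_matches.tsv")
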