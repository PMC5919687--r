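test_that("codons are assigned to MSA columns via the coding sequence", {
  a <- assign_codons("AGR", "GCTGGTCGT", c(5L, 6L, 9L))
  expect_identical(a$codon, c("GCT", "GGT", "CGT"))
  expect_identical(a$msa_column, c(5L, 6L, 9L))
  # trailing stop codon is tolerated
  a2 <- assign_codons("AGR", "GCTGGTCGTTAA", c(5L, 6L, 9L))
  expect_equal(nrow(a2), 3)
  # frameshift / translation mismatch is rejected with a diagnosis
  expect_error(assign_codons("AGR", "GCTGGTCG", "length"), "multiple of 3")
  expect_error(assign_codons("AGR", "GCTGGTAAA", c(5L, 6L, 9L)),
               "does not translate")
  expect_error(assign_codons("AGR", "GCTGGTCGTGGT", c(5L, 6L, 9L)),
               "stop codon")
})

test_that("consensus codons follow the information threshold", {
  # zero entropy: everything assigned
  cc <- consensus_codon(rep("CGT", 8))
  expect_identical(cc$bases, "CGT")
  expect_equal(cc$information, c(2, 2, 2))
  # uniform base usage: maximal entropy, nothing assigned
  cc2 <- consensus_codon(c("AAA", "CCC", "GGG", "TTT"))
  expect_identical(cc2$bases, "xxx")
  expect_equal(cc2$information, c(0, 0, 0))
  # 50/50 split sits exactly at 1 bit of information: not assigned
  cc3 <- consensus_codon(c("ACT", "GCT"))
  expect_identical(substr(cc3$bases, 1, 1), "x")
  expect_identical(substr(cc3$bases, 2, 3), "CT")
  # a 3:1 split carries ~1.19 bits: assigned
  cc4 <- consensus_codon(c("ACT", "ACT", "ACT", "GCT"))
  expect_identical(cc4$bases, "ACT")
  # modal tie -> 'x' even above threshold cannot happen; check tie handling
  cc5 <- consensus_codon(c("AAT", "TAT"), threshold_bits = 0.5)
  expect_identical(substr(cc5$bases, 1, 1), "x")
  # occupancy filter drops sparse columns
  cols <- list(`10` = rep("CGT", 6), `11` = "AAA")
  out <- consensus_codons(cols, min_occupancy = 2)
  expect_identical(out$msa_column, 10L)
})

test_that("antisense pairing verdicts follow Watson-Crick middle-base logic", {
  cI <- data.frame(msa_column = c(275L, 274L),
                   consensus = c("xCx", "xAx"), stringsAsFactors = FALSE)
  cII <- data.frame(msa_column = c(698L, 699L),
                    consensus = c("xGx", "xAx"), stringsAsFactors = FALSE)
  p <- antisense_pairing(cI, cII)
  expect_identical(p$pairs$verdict2, c("match", "mismatch"))  # C-G; A-A
  expect_identical(p$pairs$marker, c(".|.", ".x."))
  expect_equal(p$middle_base_matches, 1)
  expect_identical(p$match_positions, 275L)
  # base 1 of Class I faces base 3 of Class II after the reversal
  cI2 <- data.frame(msa_column = 276L, consensus = "Axx")
  cII2 <- data.frame(msa_column = 697L, consensus = "xTT")  # 5'->3'
  p2 <- antisense_pairing(cI2, cII2)
  expect_identical(p2$pairs$verdict1, "match")     # A vs reversed first = T
  expect_error(antisense_pairing(cI, cII[1, , drop = FALSE]), "equally many")
})

test_that("pairing is symmetric under strand swap and complement involution", {
  set.seed(12)
  bases <- c("A", "C", "G", "T", "x")
  rand_codon <- function() paste(sample(bases, 3, TRUE), collapse = "")
  cI <- data.frame(msa_column = 1:12,
                   consensus = replicate(12, rand_codon()),
                   stringsAsFactors = FALSE)
  cII <- data.frame(msa_column = 101:112,
                    consensus = replicate(12, rand_codon()),
                    stringsAsFactors = FALSE)
  p <- antisense_pairing(cI, cII)
  q <- antisense_pairing(cII, cI)
  verdicts <- function(x) sort(unlist(x$pairs[, c("verdict1", "verdict2",
                                                  "verdict3")]))
  expect_identical(unname(verdicts(p)), unname(verdicts(q)))
  expect_equal(p$middle_base_matches, q$middle_base_matches)

  # complementing every Class II codon turns matches into mismatches of
  # identical bases and leaves unassigned pairs unassigned
  comp <- c(A = "T", C = "G", G = "C", T = "A", x = "x")
  cII_c <- cII
  cII_c$consensus <- vapply(strsplit(cII$consensus, ""), function(b)
    paste(comp[b], collapse = ""), "")
  pc <- antisense_pairing(cI, cII_c)
  for (k in 1:3) {
    v0 <- p$pairs[[paste0("verdict", k)]]
    v1 <- pc$pairs[[paste0("verdict", k)]]
    expect_true(all(v1[v0 == "match"] == "mismatch"))
    expect_true(all(v1[v0 == "unassigned"] == "unassigned"))
    # and the new mismatches born from old matches pair identical bases
    a <- substr(p$pairs$classI_codon, k, k)
    b <- substr(pc$pairs$classII_codon_paired, k, k)
    expect_true(all(a[v0 == "match"] == b[v0 == "match"]))
    # any new match must come from a former mismatch
    expect_true(all(v0[v1 == "match"] == "mismatch"))
  }
})

test_that("the generator's codon design survives the assignment pipeline", {
  specI <- synthetic_cohort_spec(51, "I", n_chains = 12)
  specII <- synthetic_cohort_spec(52, "II", n_chains = 12)
  dirI <- withr::local_tempdir(); dirII <- withr::local_tempdir()
  cohI <- generate_cohort(specI, dirI)
  cohII <- generate_cohort(specII, dirII)

  reconstruct <- function(coh, path_msa, cls) {
    msa <- read_msa(path_msa)
    assignments <- lapply(coh$toys, function(t) {
      map <- build_renumber_map(t$chain, msa)
      prot <- chain_sequence(t$chain)
      assign_codons(prot, coh$seqdata$cds[[t$truth$structure_id]],
                    map$entries$msa_column)
    })
    codon_columns(assignments)
  }
  colsI <- reconstruct(cohI, cohI$paths$msa, "I")
  window <- as.character(272:285)
  consI <- consensus_codons(colsI[window])
  expect_equal(consI$consensus,
               cohI$seqdata$expected_consensus$consensus[
                 match(consI$msa_column,
                       cohI$seqdata$expected_consensus$msa_column)])

  colsII <- reconstruct(cohII, cohII$paths$msa, "II")
  consII <- consensus_codons(colsII[as.character(688:701)])

  # pipeline-route pairing reproduces the generator truth exactly
  truth <- synthetic_pairing_truth(cohI$seqdata, cohII$seqdata)
  got <- antisense_pairing(
    consI[order(consI$msa_column), c("msa_column", "consensus")],
    consII[order(-consII$msa_column), c("msa_column", "consensus")])
  expect_identical(got$pairs$marker, truth$pairs$marker)
  expect_equal(got$middle_base_matches, truth$middle_base_matches)
  # the designed windows carry planted complementary middle bases
  expect_gte(truth$middle_base_matches, 3)
  expect_true(all(c(275L, 281L, 284L) %in% truth$match_positions))
})
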