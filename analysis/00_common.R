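# Shared paths and loaders for the numbered analysis scripts. Heavy
# intermediates (structures, renumbered models, mapping tables) live under
# scratch/; the small summary tables each script reports go to results/.

library(aarsmotifs)

ROOT <- normalizePath(".")
SCRATCH <- file.path(ROOT, "scratch", "analysis")
RESULTS <- file.path(ROOT, "results")
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

COHORT_SEED <- c(I = 101L, II = 102L)
COHORT_N <- 200L

cohort_dir <- function(cls) file.path(SCRATCH, paste0("cohort_", cls))

cohort_spec <- function(cls) {
  synthetic_cohort_spec(COHORT_SEED[[cls]], cls, n_chains = COHORT_N,
                        m1_fraction = 0.5)
}

load_cohort_chains <- function(cls) {
  dir <- cohort_dir(cls)
  ann <- read_annotation_table(file.path(dir, "annotations.tsv"))
  chains <- list()
  for (i in seq_len(nrow(ann))) {
    f <- file.path(dir, "structures",
                   paste0(ann$pdb_id[i], "_", ann$chain[i], ".pdb"))
    chains[[paste(ann$pdb_id[i], ann$chain[i], sep = "_")]] <-
      suppressMessages(parse_structure(f, structure_id = ann$pdb_id[i]))[[
        ann$chain[i]]]
  }
  list(annotations = ann, chains = chains, dir = dir)
}

require_stage <- function(path, hint) {
  if (!file.exists(path))
    stop("missing prerequisite artifact: ", path, "\n  run ", hint,
         " first", call. = FALSE)
}

write_result <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("  wrote ", path)
  invisible(path)
}
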