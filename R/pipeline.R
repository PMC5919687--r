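# Pipeline orchestration: ties dataset assembly, renumbering, interaction
# profiling, geometry and codon analysis into one configurable run with
# TSV/JSON reports and a machine-readable manifest.

#' Pipeline configuration
#'
#' @param structures_dir directory of PDB files (one chain cohort).
#' @param annotations path to the chain annotation TSV.
#' @param msa path to the class MSA FASTA.
#' @param cds optional path to the coding-sequence FASTA (codon stage).
#' @param aars_class "I" or "II".
#' @param out_dir output directory.
#' @param identity_threshold clustering threshold (percent).
#' @param mapping_min_identity renumbering refusal threshold (percent).
#' @param consensus_bits consensus information threshold (bits).
#' @param interaction_config cutoff overrides, see
#'   \code{\link{default_interaction_config}}.
#' @param seed integer seed (stages themselves are deterministic; recorded in
#'   the manifest).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(structures_dir, annotations, msa, cds = NULL,
                            aars_class = c("II", "I"), out_dir,
                            identity_threshold = 95,
                            mapping_min_identity = 40,
                            consensus_bits = 1.0,
                            interaction_config = list(), seed = 1L) {
  aars_class <- match.arg(aars_class)
  stopifnot(identity_threshold > 0, mapping_min_identity > 0,
            consensus_bits > 0)
  structure(list(structures_dir = structures_dir, annotations = annotations,
                 msa = msa, cds = cds, aars_class = aars_class,
                 out_dir = out_dir, identity_threshold = identity_threshold,
                 mapping_min_identity = mapping_min_identity,
                 consensus_bits = consensus_bits,
                 interaction_config = interaction_config,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{pipeline_config}}.
#'
#' @param path YAML file.
#' @return \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the analysis pipeline
#'
#' Stages: \code{dataset} (parse structures, assign binding modes, cluster,
#' pick representatives), \code{renumber} (MSA mapping, renumbered
#' structures, mapping tables, failure list), \code{interactions} (profile
#' M1 representatives, build the preference matrix), \code{geometry}
#' (motif observations, per-mode summaries, Mann-Whitney tests, motif
#' superposition) and \code{codons} (codon assignment, consensus,
#' per-column tables). Later stages require earlier ones; requesting a stage
#' without its prerequisites is an error. Reports are written under the
#' configured output directory together with a JSON manifest of per-stage
#' counts.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages subset of stages to run.
#' @return list with the stage results and the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("dataset", "renumber", "interactions",
                                    "geometry", "codons")) {
  all_stages <- c("dataset", "renumber", "interactions", "geometry",
                  "codons")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- list(renumber = "dataset", interactions = "renumber",
               geometry = "renumber", codons = "renumber")
  for (s in stages) {
    pre <- need[[s]]
    if (!is.null(pre) && !pre %in% stages)
      stop(sprintf("stage '%s' requires stage '%s'", s, pre))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, aars_class = config$aars_class,
                   config = config[c("identity_threshold",
                                     "mapping_min_identity",
                                     "consensus_bits")])
  res <- list()

  ## ---- dataset ----------------------------------------------------------
  ann <- read_annotation_table(config$annotations)
  files <- file.path(config$structures_dir,
                     paste0(ann$pdb_id, "_", ann$chain, ".pdb"))
  chains <- list()
  for (i in seq_along(files)) {
    parsed <- parse_structure(files[i], structure_id = ann$pdb_id[i])
    chains[[paste(ann$pdb_id[i], ann$chain[i], sep = "_")]] <-
      parsed[[ann$chain[i]]]
  }
  dataset <- build_dataset(chains, ann, config$identity_threshold)
  write_dataset(dataset, tsv = file.path(config$out_dir, "dataset.tsv"),
                json = file.path(config$out_dir, "dataset.json"))
  res$dataset <- dataset
  res$chains <- chains
  manifest$dataset <- list(
    n_chains = nrow(dataset),
    n_m1 = sum(dataset$binding_mode == "M1"),
    n_m2 = sum(dataset$binding_mode == "M2"),
    n_clusters = length(unique(dataset$cluster)))
  if (identical(stages, "dataset") || !"renumber" %in% stages)
    return(c(res, list(manifest = manifest)))

  ## ---- renumber ---------------------------------------------------------
  msa <- read_msa(config$msa)
  maps <- lapply(names(chains), function(k)
    build_renumber_map(chains[[k]], msa, config$mapping_min_identity))
  names(maps) <- names(chains)
  renumbered <- list()
  for (k in names(chains)) {
    if (!isTRUE(maps[[k]]$failed))
      renumbered[[k]] <- renumber_chain(chains[[k]], maps[[k]])
  }
  dir.create(file.path(config$out_dir, "renumbered"), showWarnings = FALSE)
  for (k in names(renumbered))
    write_structure(renumbered[[k]],
                    file.path(config$out_dir, "renumbered",
                              paste0(k, ".pdb")))
  write_mapping_table(maps, file.path(config$out_dir, "mapping.tsv"))
  write_failure_list(maps, file.path(config$out_dir, "mapping_failures.txt"))
  motif <- Filter(function(m) m$aars_class == config$aars_class,
                  motif_definitions())[[1]]
  located <- vapply(renumbered, function(ch)
    locate_motif(ch, motif)$found, TRUE)
  res$maps <- maps; res$renumbered <- renumbered; res$motif <- motif
  manifest$renumber <- list(
    n_mapped = length(renumbered),
    n_failed = sum(vapply(maps, function(m) isTRUE(m$failed), TRUE)),
    n_motif_located = sum(located),
    n_motif_missing = sum(!located))

  ## ---- interactions -----------------------------------------------------
  if ("interactions" %in% stages) {
    key_m1 <- paste(dataset$pdb_id, dataset$chain,
                    sep = "_")[dataset$representative_m1]
    key_m1 <- intersect(key_m1, names(renumbered))
    records <- list()
    presence <- list()
    type_of <- stats::setNames(dataset$type,
                               paste(dataset$pdb_id, dataset$chain,
                                     sep = "_"))
    for (k in key_m1) {
      ch <- renumbered[[k]]
      for (lig in ch$ligands) {
        if (!lig$has_adenosine_phosphate) next
        r <- annotate_interactions(ch, lig, config$interaction_config)
        if (nrow(r)) {
          r$aars_type <- type_of[[k]]
          r$chain_key <- k
          records[[length(records) + 1]] <- r
        }
      }
      pos <- vapply(polymer_residues(ch), function(x) x$number, 1L)
      presence[[length(presence) + 1]] <-
        data.frame(aars_type = type_of[[k]], chain_key = k,
                   position = pos[pos > 0])
    }
    records <- if (length(records)) do.call(rbind, records) else
      data.frame()
    presence <- if (length(presence)) do.call(rbind, presence) else NULL
    imat <- if (nrow(records)) build_interaction_matrix(records, presence)
            else data.frame()
    write_interaction_reports(
      records, imat,
      records_tsv = file.path(config$out_dir, "interactions.tsv"),
      matrix_tsv = file.path(config$out_dir, "interaction_matrix.tsv"),
      matrix_json = file.path(config$out_dir, "interaction_matrix.json"))
    res$interactions <- records; res$interaction_matrix <- imat
    manifest$interactions <- list(
      n_complexes = length(key_m1),
      n_records = nrow(records),
      n_matrix_cells = nrow(imat))
  }

  ## ---- geometry ---------------------------------------------------------
  if ("geometry" %in% stages) {
    mode_of <- stats::setNames(dataset$binding_mode,
                               paste(dataset$pdb_id, dataset$chain,
                                     sep = "_"))
    obs <- list()
    for (k in names(renumbered)) {
      o <- motif_observation(renumbered[[k]], motif, mode_of[[k]])
      if (!is.null(o)) obs[[length(obs) + 1]] <- o
    }
    obs <- do.call(rbind, obs)
    summary <- summarize_geometry(obs)
    sup <- list()
    for (md in c("M1", "M2")) {
      keys <- names(renumbered)[vapply(names(renumbered), function(k)
        mode_of[[k]] == md, TRUE)]
      if (length(keys) >= 2)
        sup[[md]] <- superpose_motifs(renumbered[keys], motif)
    }
    utils::write.table(obs, file.path(config$out_dir, "observations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(groups = summary$groups, tests = summary$tests,
           mean_rmsd = lapply(sup, function(s) s$mean_rmsd)),
      file.path(config$out_dir, "geometry_summary.json"),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$observations <- obs; res$geometry_summary <- summary
    res$superposition <- sup
    manifest$geometry <- list(
      n_observations = nrow(obs),
      n_theta_defined = sum(!is.na(obs$theta)),
      n_theta_undefined = sum(is.na(obs$theta)))
  }

  ## ---- codons -----------------------------------------------------------
  if ("codons" %in% stages && !is.null(config$cds)) {
    cds <- Biostrings::readDNAStringSet(config$cds)
    cdsv <- stats::setNames(as.character(cds), sub("\\s.*$", "", names(cds)))
    assignments <- list()
    rejected <- 0L
    for (k in names(renumbered)) {
      map <- maps[[k]]
      sid <- map$structure_id
      if (!sid %in% names(cdsv)) next
      ch <- chains[[k]]
      prot <- chain_sequence(ch, nonstandard = "parent")
      colmap <- rep(NA_integer_, nchar(prot))
      res_nums <- vapply(polymer_residues(ch), function(r)
        paste(r$number, r$icode), "")
      ek <- paste(map$entries$author_number, map$entries$icode)
      colmap[match(ek, res_nums)] <- map$entries$msa_column
      if (anyNA(colmap)) next  # only fully mapped rows contribute codons
      a <- tryCatch(assign_codons(prot, cdsv[[sid]], colmap),
                    error = function(e) { rejected <<- rejected + 1L; NULL })
      if (!is.null(a)) assignments[[length(assignments) + 1]] <- a
    }
    cols <- codon_columns(assignments)
    cons <- consensus_codons(cols, config$consensus_bits)
    utils::write.table(cons, file.path(config$out_dir, "consensus_codons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$codon_columns <- cols; res$consensus <- cons
    manifest$codons <- list(n_sequences = length(assignments),
                            n_rejected = rejected,
                            n_columns = nrow(cons))
  }

  manifest$hash <- digest_manifest(manifest)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res
}

digest_manifest <- function(manifest) {
  # order-stable hash of the manifest counts (no external digest dependency)
  s <- jsonlite::toJSON(manifest[sort(names(manifest))], auto_unbox = TRUE,
                        digits = NA)
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2147483647
}

#' Residue frequency table around an alignment position
#'
#' Per-column amino-acid frequencies for positions p-3 .. p+3 of a
#' renumbered cohort: the numeric counterpart of a sequence logo.
#'
#' @param chains list of renumbered chains.
#' @param position central renumbered position.
#' @param flank number of columns on each side (default 3).
#' @return data.frame: column, residue, count, frequency.
#' @export
sequence_logo_table <- function(chains, position, flank = 3) {
  cols <- (position - flank):(position + flank)
  rows <- list()
  for (col in cols) {
    letters_at <- character(0)
    for (ch in chains) {
      res <- polymer_residues(ch)
      num <- vapply(res, function(r) r$number, 1L)
      i <- which(num == col)
      if (length(i) == 1)
        letters_at <- c(letters_at, AA_THREE_TO_ONE[res[[i]]$name] %||% "X")
    }
    if (length(letters_at) == 0) {
      rows[[length(rows) + 1]] <- data.frame(column = col, residue = NA,
                                             count = 0L, frequency = 0)
      next
    }
    tab <- table(letters_at)
    rows[[length(rows) + 1]] <- data.frame(
      column = col, residue = names(tab), count = as.integer(tab),
      frequency = as.numeric(tab) / length(letters_at),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
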