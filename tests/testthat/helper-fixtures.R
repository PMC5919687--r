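# Small fixture builders (all in code; no stored data files).

make_residue <- function(name, number, coords, icode = "",
                         is_polymer = TRUE) {
  nm <- names(coords)
  xyz <- do.call(rbind, coords)
  new_residue(number, name,
              atom_table(nm, vapply(nm, aarsmotifs:::guess_element, ""),
                         xyz[, 1], xyz[, 2], xyz[, 3]),
              icode = icode, is_polymer = is_polymer)
}

# a minimal well-formed residue with CA at `ca` (backbone only)
backbone_residue <- function(name, number, ca) {
  make_residue(name, number, list(N = ca + c(-1.2, 0.8, 0), CA = ca,
                                  C = ca + c(1.2, 0.8, 0),
                                  O = ca + c(1.2, 2.0, 0)))
}

# short toy chain of backbone-only residues with the given one-letter seq
toy_chain <- function(seq1, structure_id = "toy", chain_id = "A",
                      spacing = 3.8) {
  letters1 <- strsplit(seq1, "")[[1]]
  three <- stats::setNames(names(aarsmotifs:::AA_THREE_TO_ONE),
                           aarsmotifs:::AA_THREE_TO_ONE)
  res <- lapply(seq_along(letters1), function(i)
    backbone_residue(three[[letters1[i]]], i, c(spacing * i, 0, 0)))
  structure_chain(structure_id, chain_id, res)
}

random_aa <- function(n) {
  paste(sample(unname(aarsmotifs:::AA_THREE_TO_ONE), n, replace = TRUE),
        collapse = "")
}
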