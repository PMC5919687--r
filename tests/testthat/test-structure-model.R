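test_that("PDB writing and parsing round-trip coordinates at 3 decimals", {
  set.seed(11)
  spec <- synthetic_cohort_spec(11, "II", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$chain, f)
  parsed <- parse_structure(f)
  expect_length(parsed, 1)
  ch <- parsed[["A"]]
  expect_equal(length(polymer_residues(ch)),
               length(polymer_residues(toy$chain)))
  orig <- do.call(rbind, lapply(toy$chain$residues,
                                function(r) aarsmotifs:::atom_xyz(r$atoms)))
  back <- do.call(rbind, lapply(ch$residues,
                                function(r) aarsmotifs:::atom_xyz(r$atoms)))
  expect_equal(back, orig, tolerance = 1e-3, ignore_attr = TRUE)
  # ligand survives with its component code and flags
  expect_length(ch$ligands, 1)
  expect_true(ch$ligands[[1]]$has_adenosine_phosphate)

  # second write of the re-parsed structure is byte-identical
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, f2)
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(parse_structure(f2)[["A"]], f3)
  expect_identical(readLines(f2), readLines(f3))
})

test_that("a single-residue file yields one chain, 1 residue, 0 ligands", {
  ch <- toy_chain("A", structure_id = "mini")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, f)
  parsed <- parse_structure(f)
  expect_length(parsed, 1)
  expect_length(parsed[["A"]]$residues, 1)
  expect_length(parsed[["A"]]$ligands, 0)
})

test_that("malformed coordinate records are reported with the line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1       bad coords here",
               "END"), f)
  expect_error(parse_structure(f), "line 1")
  expect_error(parse_structure(file.path(tempdir(), "nope.pdb")),
               "cannot read")
})

test_that("waters are excluded and contact-free ligands are dropped with a log", {
  ch <- toy_chain("AGR")
  wat <- new_ligand("HOH", atom_table("O", "O", 5, 1, 0), number = 100)
  far <- new_ligand("GOL", atom_table(c("C1", "C2"), c("C", "C"),
                                      c(90, 91), c(90, 90), c(90, 90)),
                    number = 101)
  ch$ligands <- list(wat, far)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ch, f)
  expect_message(parsed <- parse_structure(f), "dropped")
  expect_length(parsed[["A"]]$ligands, 0)
  expect_identical(attr(parsed, "dropped_ligands"), "GOL")
})

test_that("altloc keeps the highest-occupancy conformer (ties toward A)", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      4  CB AALA A   1       1.500   1.000   0.000  0.50  0.00           C",
    "ATOM      5  CB BALA A   1       2.500   1.000   0.000  0.50  0.00           C",
    "END"), f)
  ch <- parse_structure(f)[["A"]]
  r <- ch$residues[[1]]
  expect_equal(residue_atom(r, "CA")[1], 2.0)  # occupancy 0.70 wins
  expect_equal(residue_atom(r, "CB")[1], 1.5)  # tie -> altloc A
})

test_that("chain_sequence translates residues and handles nonstandard codes", {
  ch <- toy_chain("AGR")
  expect_identical(chain_sequence(ch), "AGR")
  mse <- backbone_residue("MSE", 4, c(16, 0, 0))
  ch$residues <- c(ch$residues, list(mse))
  expect_identical(chain_sequence(ch, "strict"), "AGRX")
  expect_identical(chain_sequence(ch, "parent"), "AGRM")
  empty <- structure_chain("e", "A", list())
  expect_error(chain_sequence(empty), "no polymer")
})

test_that("ligand classification follows curated codes and the atom graph", {
  expect_identical(classify_ligand("ATP"),
                   list(has_adenosine_phosphate = TRUE,
                        has_amino_acid_part = FALSE))
  expect_identical(classify_ligand("TRP"),
                   list(has_adenosine_phosphate = FALSE,
                        has_amino_acid_part = TRUE))

  # synthetic adenosine-phosphate graph (no curated code) is detected
  far <- data.frame(name = "CA", element = "C", x = 0, y = -9, z = -7)
  amp <- aarsmotifs:::build_tweezers_ligand(c(3, 3, 0), c(11, 3, 0),
                                            far, FALSE)
  fl <- classify_ligand("ZZZ", amp$atoms)
  expect_true(fl$has_adenosine_phosphate)
  expect_false(fl$has_amino_acid_part)

  # grafting a free alpha-amino-acid fragment outside the nucleotide makes
  # it an aminoacyl adenylate (both flags)
  aa <- data.frame(name = c("N8X", "CAX", "CX", "OX1", "OX2"),
                   element = c("N", "C", "C", "O", "O"),
                   x = c(30, 31.4, 32.2, 31.8, 33.4),
                   y = c(0, 0.4, 1.6, 2.7, 1.5), z = 0)
  both <- rbind(amp$atoms, aa)
  fl2 <- classify_ligand("ZZZ", both)
  expect_true(fl2$has_adenosine_phosphate)
  expect_true(fl2$has_amino_acid_part)

  # pure function: repeated calls agree
  expect_identical(classify_ligand("ZZZ", both), fl2)

  # unknown code with unmatchable graph: both flags false, logged
  expect_message(
    fl3 <- classify_ligand("QQQ", atom_table(c("C1", "C2"), c("C", "C"),
                                             c(0, 1.5), c(0, 0), c(0, 0))),
    "no known moiety")
  expect_false(fl3$has_adenosine_phosphate)
  expect_false(fl3$has_amino_acid_part)
})

test_that("bond inference respects covalent radii plus slack", {
  at <- atom_table(c("C1", "C2", "C3"), c("C", "C", "C"),
                   x = c(0, 1.5, 4.0), y = 0, z = 0)
  b <- infer_bonds(at)
  expect_equal(nrow(b), 1)
  expect_equal(sort(b[1, ]), c(1, 2))
})
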