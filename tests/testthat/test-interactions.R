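# Constructed-geometry checks of the individual interaction rules, plus the
# fragment partition and matrix logic.

minimal_chain <- function(residues) structure_chain("ix", "A", residues)

test_that("backbone hydrogen bonds are detected with the donor-angle proxy", {
  res <- make_residue("ALA", 5, list(N = c(0, 1.4, 0), CA = c(0, 0, 0),
                                     C = c(1.2, -0.8, 0), O = c(1.2, -2, 0),
                                     CB = c(-1.4, -0.5, 0)))
  lig <- new_ligand("XXO", atom_table(c("O1", "C1"), c("O", "C"),
                                      x = c(0, 0), y = c(4.3, 5.6),
                                      z = c(0, 0)), number = 9)
  rec <- suppressMessages(
    annotate_interactions(minimal_chain(list(res)), lig))
  expect_equal(nrow(rec), 1)
  expect_identical(rec$kind, "hydrogen_bond")
  expect_true(rec$backbone)
  expect_equal(rec$distance, 2.9, tolerance = 1e-6)

  # acceptor behind the donor (angle proxy < 100 degrees): no bond
  lig2 <- new_ligand("XXO", atom_table(c("O1", "C1"), c("O", "C"),
                                       x = c(0.6, 0.6), y = c(-1.2, -2.5),
                                       z = c(2, 2)), number = 9)
  rec2 <- suppressMessages(
    annotate_interactions(minimal_chain(list(res)), lig2))
  expect_false("hydrogen_bond" %in% rec2$kind)
})

test_that("salt bridges use charged-group centroids and suppress their hydrogen bonds", {
  arg <- make_residue("ARG", 7, list(
    N = c(0, -1.4, 0), CA = c(0, 0, 0), C = c(1.2, -0.8, 0),
    O = c(1.2, -2, 0), CB = c(0, 1.5, 0), CG = c(0, 2.5, 0),
    CD = c(0, 3.5, 0), NE = c(0.8, 4.1, 0), CZ = c(0, 4.6, 0),
    NH1 = c(0.7, 5.4, 0), NH2 = c(-0.7, 5.4, 0)))
  # phosphate group ~4.5 A above the guanidinium centroid
  lig <- new_ligand("XPO", atom_table(
    c("P", "O1", "O2", "O3", "O4"), c("P", "O", "O", "O", "O"),
    x = c(0, 1.5, -1.5, 0, 0), y = c(9.3, 9.3, 9.3, 9.3, 10.8),
    z = c(0, 0, 0, 1.5, 0)), number = 10)
  rec <- suppressMessages(annotate_interactions(minimal_chain(list(arg)), lig))
  expect_true("salt_bridge" %in% rec$kind)
  # NH1/NH2 are within hydrogen-bond range of the phosphate oxygens, but the
  # salt bridge absorbs those contacts
  expect_false("hydrogen_bond" %in% rec$kind)
})

test_that("pi-cation fires for a cation over an aromatic ring plane", {
  spec <- synthetic_cohort_spec(31, "II", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  rec <- suppressMessages(
    annotate_interactions(toy$chain, toy$chain$ligands[[1]]))
  pc <- rec[rec$kind == "pi_cation", ]
  expect_equal(nrow(pc), 1)
  expect_identical(pc$fragment, "adenine")
  expect_identical(pc$res_name, "ARG")
  expect_lte(pc$distance, 6.0)
})

test_that("pi-stacking distinguishes parallel and tilted ring planes", {
  ring_xy <- function(z, tilt = 0) {
    a <- seq(0, 300, by = 60) * pi / 180
    x <- 1.39 * cos(a); y <- 1.39 * sin(a)
    zz <- z + x * tan(tilt * pi / 180)
    list(x = x, y = y, z = zz)
  }
  phe_ring <- ring_xy(0)
  phe <- make_residue("PHE", 3, c(
    list(N = c(3.4, 0.6, -2.9), CA = c(2.5, 0, -2.4), C = c(3.0, -1, -3.2),
         O = c(3.0, -2.2, -3.0)),
    stats::setNames(lapply(1:6, function(i)
      c(phe_ring$x[i], phe_ring$y[i], phe_ring$z[i])),
      c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))))
  lig_ring <- function(tilt) {
    r <- ring_xy(3.6, tilt)
    new_ligand("XAR", atom_table(paste0("C", 1:6), rep("C", 6),
                                 r$x, r$y, r$z), number = 11)
  }
  rec_par <- suppressMessages(
    annotate_interactions(minimal_chain(list(phe)), lig_ring(0)))
  expect_true("pi_stacking" %in% rec_par$kind)
  # ~45 degree tilt falls between the parallel and perpendicular windows
  rec_mid <- suppressMessages(
    annotate_interactions(minimal_chain(list(phe)), lig_ring(45)))
  expect_false("pi_stacking" %in% rec_mid$kind)
})

test_that("hydrophobic contacts require apolar carbons on both sides", {
  leu <- make_residue("LEU", 4, list(
    N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, 0.8, 0),
    O = c(1.2, 2.0, 0), CB = c(0, -1.5, 0), CG = c(0, -2.6, 0),
    CD1 = c(1.2, -3.3, 0), CD2 = c(-1.2, -3.3, 0)))
  # apolar ligand carbon 3.8 A from CD1
  lig <- new_ligand("XHC", atom_table(c("C1", "C2"), c("C", "C"),
                                      x = c(1.2, 2.7), y = c(-7.1, -7.1),
                                      z = c(0, 0)), number = 12)
  rec <- suppressMessages(annotate_interactions(minimal_chain(list(leu)), lig))
  expect_identical(unique(rec$kind), "hydrophobic")
  # polar carbon (bonded to O) at the same distance: nothing
  lig2 <- new_ligand("XHO", atom_table(c("C1", "O1"), c("C", "O"),
                                       x = c(1.2, 2.6), y = c(-7.1, -7.1),
                                       z = c(0, 0)), number = 13)
  rec2 <- suppressMessages(
    annotate_interactions(minimal_chain(list(leu)), lig2))
  expect_false("hydrophobic" %in% rec2$kind)
})

test_that("a lone sodium near a phosphate oxygen yields one metal complex", {
  spec <- synthetic_cohort_spec(32, "II", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  ch <- toy$chain
  lig <- ch$ligands[[1]]
  o1p <- as.numeric(lig$atoms[lig$atoms$name == "O1P", c("x", "y", "z")])
  na_pos <- o1p + c(0, 0, 2.2)
  met <- new_ligand("NA", atom_table("NA", "NA", na_pos[1], na_pos[2],
                                     na_pos[3]), number = 400)
  ch$ligands <- c(ch$ligands, list(met))
  rec <- suppressMessages(annotate_interactions(ch, lig))
  mc <- rec[rec$kind == "metal_complex", ]
  expect_equal(nrow(mc), 1)
  expect_lte(mc$distance, 3.0)
})

test_that("fragment labels partition nucleotide ligand atoms", {
  spec <- synthetic_cohort_spec(33, "I", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  lig <- toy$chain$ligands[[1]]
  fr <- assign_fragment(lig)
  expect_length(fr, nrow(lig$atoms))
  expect_setequal(unique(fr), c("phosphate", "ribose", "adenine"))
  # P and its oxygens
  expect_identical(unique(fr[lig$atoms$element == "P"]), "phosphate")
  expect_identical(fr[lig$atoms$name == "N6"], "adenine")
  expect_identical(fr[lig$atoms$name == "C1'"], "ribose")
  # non-nucleotide ligand: everything amino_acid_part
  aa <- new_ligand("TRP", atom_table(c("N", "CA", "C", "O", "CB"),
                                     c("N", "C", "C", "O", "C"),
                                     x = c(0, 1.4, 2.2, 2.0, 1.6),
                                     y = c(0, 0.4, 1.5, 2.7, -1.0), z = 0),
                   number = 14)
  expect_identical(unique(assign_fragment(aa)), "amino_acid_part")
})

test_that("interaction records are invariant under rigid motions", {
  set.seed(99)
  spec <- synthetic_cohort_spec(34, "II", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  rec0 <- suppressMessages(
    annotate_interactions(toy$chain, toy$chain$ligands[[1]]))
  for (i in 1:3) {
    R <- random_rotation()
    tr <- stats::rnorm(3, 0, 20)
    moved <- transform_chain(toy$chain, R, tr)
    rec <- suppressMessages(
      annotate_interactions(moved, moved$ligands[[1]]))
    expect_equal(rec[, c("kind", "res_number", "fragment", "backbone")],
                 rec0[, c("kind", "res_number", "fragment", "backbone")])
    expect_equal(rec$distance, rec0$distance, tolerance = 1e-9)
  }
})

test_that("every record satisfies its own cutoff (self-consistency sweep)", {
  cfg <- default_interaction_config()
  cutoffs <- c(hydrogen_bond = cfg$hbond_dist, salt_bridge = cfg$saltbridge_dist,
               pi_stacking = cfg$pistack_dist, pi_cation = cfg$pication_dist,
               hydrophobic = cfg$hydrophobic_dist, metal_complex = cfg$metal_dist)
  for (cls in c("I", "II")) {
    spec <- synthetic_cohort_spec(35, cls, n_chains = 4, m1_fraction = 1)
    for (i in 1:4) {
      toy <- generate_toy_structure(spec, i)
      rec <- suppressMessages(
        annotate_interactions(toy$chain, toy$chain$ligands[[1]]))
      expect_true(all(rec$distance <= cutoffs[rec$kind] + 1e-9))
    }
  }
})

test_that("the interaction matrix reports preferences, ties and no-contact", {
  records <- data.frame(
    kind = c("salt_bridge", "salt_bridge", "salt_bridge", "hydrogen_bond",
             "pi_cation", "pi_stacking", "pi_cation",
             "hydrogen_bond"),
    res_number = c(698L, 698L, 698L, 698L, 1786L, 1786L, 1786L, 700L),
    res_name = "ARG",
    fragment = c("phosphate", "phosphate", "phosphate", "phosphate",
                 "adenine", "adenine", "adenine", "adenine"),
    aars_type = c("AspRS", "AspRS", "LysRS-II", "AspRS",
                  "AspRS", "AspRS", "LysRS-II", "AspRS"),
    chain_key = c("a", "b", "e", "c", "a", "b", "e", "a"),
    stringsAsFactors = FALSE)
  presence <- data.frame(
    aars_type = c("AspRS", "AspRS", "AspRS", "LysRS-II", "AspRS"),
    chain_key = c("a", "b", "c", "e", "d"),
    position = c(698L, 698L, 698L, 698L, 698L))
  m <- build_interaction_matrix(records, presence)
  # position 700 observed in a single aaRS type is discarded
  expect_false(700 %in% m$position)
  asp698 <- m[m$position == 698 & m$aars_type == "AspRS", ]
  expect_equal(asp698$salt_bridge, 2L)
  expect_equal(asp698$hydrogen_bond, 1L)
  expect_identical(asp698$preferred, "salt_bridge")
  expect_true(is.na(asp698$preferred2))
  # chain d contributes position 698 but has no record there: no-contact
  expect_equal(asp698$no_contact, 1L)
  # tie at 1786 for AspRS: two preferred kinds reported
  t1786 <- m[m$position == 1786 & m$aars_type == "AspRS", ]
  expect_identical(t1786$preferred, "pi_stacking")
  expect_identical(t1786$preferred2, "pi_cation")
  # single observation of one kind: that kind preferred, no tie
  lys1786 <- m[m$position == 1786 & m$aars_type == "LysRS-II", ]
  expect_identical(lys1786$preferred, "pi_cation")
  expect_true(is.na(lys1786$preferred2))
  # empty input: empty matrix
  expect_equal(nrow(build_interaction_matrix(records[0, ], NULL)), 0)
})
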