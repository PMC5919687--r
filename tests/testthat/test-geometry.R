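test_that("alpha-carbon distance matches closed forms and planted values", {
  a <- backbone_residue("ALA", 1, c(0, 0, 0))
  b <- backbone_residue("GLY", 2, c(3, 4, 0))
  expect_equal(ca_distance(a, b), 5)                   # 3-4-5 triangle
  spec <- synthetic_cohort_spec(41, "II", n_chains = 4, m1_fraction = 0.5)
  for (i in 1:4) {
    toy <- generate_toy_structure(spec, i)
    d <- ca_distance(toy$chain$residues[[12]], toy$chain$residues[[27]])
    expect_equal(d, toy$truth$ca_distance, tolerance = 1e-6)
  }
  noca <- make_residue("ALA", 3, list(CB = c(1, 1, 1)))
  expect_message(expect_true(is.na(ca_distance(a, noca))), "missing CA")
})

test_that("side-chain vectors pick the most distant carbon; glycine undefined", {
  gly <- backbone_residue("GLY", 1, c(0, 0, 0))
  expect_null(side_chain_vector(gly))
  ala <- make_residue("ALA", 2, list(CA = c(0, 0, 0), CB = c(1.2, 0.9, 0),
                                     N = c(-1.2, 0.8, 0), C = c(1.2, -0.8, 0)))
  expect_equal(side_chain_vector(ala), c(1.2, 0.9, 0))
  # idealized arginine: CZ is the farthest carbon by exhaustive check
  arg <- make_residue("ARG", 3, list(
    N = c(-1.2, 0.8, 0), CA = c(0, 0, 0), C = c(1.2, -0.8, 0),
    O = c(1.2, -2, 0), CB = c(0.4, 1.4, 0.2), CG = c(0.2, 2.8, 0.3),
    CD = c(0.6, 4.1, 0.1), NE = c(0.4, 5.3, 0.6), CZ = c(0.6, 6.6, 0.2),
    NH1 = c(1.3, 7.3, 1.0), NH2 = c(-0.2, 7.2, -0.6)))
  sc <- side_chain_vector(arg)
  carbons <- arg$atoms[arg$atoms$element == "C" &
                         !(arg$atoms$name %in% c("CA", "C")), ]
  dists <- sqrt(carbons$x^2 + carbons$y^2 + carbons$z^2)
  expect_identical(carbons$name[which.max(dists)], "CZ")
  expect_equal(sc, as.numeric(carbons[carbons$name == "CZ",
                                      c("x", "y", "z")]))
  # tie on distance breaks toward the smaller atom name
  tie <- make_residue("LEU", 4, list(
    CA = c(0, 0, 0), N = c(-1.2, 0.8, 0), C = c(1.2, -0.8, 0),
    CD2 = c(0, 0, 2), CD1 = c(2, 0, 0)))
  expect_equal(side_chain_vector(tie), c(2, 0, 0))     # CD1 before CD2
})

test_that("side-chain angles hit the stated limits and planted values", {
  mk <- function(cb) make_residue("ALA", 1, list(CA = c(0, 0, 0), CB = cb,
                                                 N = c(-1, 1, 0),
                                                 C = c(1, -1, 0)))
  mk2 <- function(cb) make_residue("ALA", 2, list(CA = c(9, 0, 0),
                                                  CB = c(9, 0, 0) + cb,
                                                  N = c(8, 1, 0),
                                                  C = c(10, -1, 0)))
  expect_equal(side_chain_angle(mk(c(0, 0, 1.5)), mk2(c(0, 0, 1.5))), 0)
  expect_equal(side_chain_angle(mk(c(0, 0, 1.5)), mk2(c(0, 0, -1.5))), 180)
  expect_equal(side_chain_angle(mk(c(0, 1.5, 0)), mk2(c(0, 0, 1.5))), 90,
               tolerance = 1e-6)
  # symmetry
  a <- mk(c(0.3, 1.2, 0.8)); b <- mk2(c(-0.7, 0.4, 1.1))
  expect_equal(side_chain_angle(a, b), side_chain_angle(b, a))
  # glycine rule propagates to NA
  expect_true(is.na(side_chain_angle(backbone_residue("GLY", 1, c(0, 0, 0)),
                                     b)))
})

test_that("descriptors are invariant under rigid motions", {
  set.seed(7)
  spec <- synthetic_cohort_spec(42, "I", n_chains = 2, m1_fraction = 1)
  toy <- generate_toy_structure(spec, 1)
  r1 <- toy$chain$residues[[12]]; r2 <- toy$chain$residues[[27]]
  d0 <- ca_distance(r1, r2); t0 <- side_chain_angle(r1, r2)
  for (i in 1:5) {
    moved <- transform_chain(toy$chain, random_rotation(),
                             stats::rnorm(3, 0, 30))
    m1 <- moved$residues[[12]]; m2 <- moved$residues[[27]]
    expect_equal(ca_distance(m1, m2), d0, tolerance = 1e-9)
    expect_equal(side_chain_angle(m1, m2), t0, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches exact enumeration for all group sizes <= 8", {
  set.seed(8)
  for (rep in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # mixed continuous and tied data
    x <- sample(c(stats::rnorm(n1), sample(1:3, n1, TRUE)), n1)
    y <- sample(c(stats::rnorm(n2), sample(1:3, n2, TRUE)), n2)
    got <- mann_whitney_u(x, y)
    expect_identical(got$method, "exact")
    expect_equal(got$p, mw_enumeration_oracle(x, y), tolerance = 1e-12)
  }
  # tie-free exact p agrees with the reference implementation
  for (rep in 1:10) {
    x <- stats::rnorm(6); y <- stats::rnorm(7, 0.5)
    got <- mann_whitney_u(x, y)
    ref <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(got$p, ref, tolerance = 1e-12)
  }
  # identical groups: U = n^2/2 and p ~ 1
  z <- c(1, 2, 3, 4)
  got <- mann_whitney_u(z, z)
  expect_equal(got$U, length(z)^2 / 2)
  expect_equal(got$p, 1)
})

test_that("large-sample Mann-Whitney uses the tie-corrected normal approximation", {
  set.seed(9)
  x <- round(stats::rnorm(30), 1); y <- round(stats::rnorm(35, 0.8), 1)
  got <- mann_whitney_u(x, y)
  expect_identical(got$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))$p.value
  expect_equal(got$p, ref, tolerance = 1e-9)
})

test_that("geometry summaries separate modes and handle undefined angles", {
  obs <- data.frame(
    structure_id = sprintf("s%02d", 1:10), chain_id = "A",
    motif = "Backbone Brackets", position_a = 274L, position_b = 1361L,
    ca_distance = c(17.1, 17.9, 18.2, 17.6, 18.0, 18.4, 18.6, 18.9, 18.3, 18.7),
    theta = c(140, 150, NA, 145, 148, 139, 142, NA, 150, 141),
    binding_mode = rep(c("M1", "M2"), each = 5), stringsAsFactors = FALSE)
  s <- summarize_geometry(obs)
  m1 <- s$groups[s$groups$binding_mode == "M1", ]
  expect_equal(m1$n, 5)
  expect_equal(m1$n_theta, 4)                       # listwise theta exclusion
  expect_equal(m1$distance_mean, mean(obs$ca_distance[1:5]))
  expect_equal(m1$theta_sd, sd(obs$theta[1:5], na.rm = TRUE))
  expect_true(all(c("ca_distance", "theta") %in% s$tests$descriptor))
  expect_identical(unique(s$tests$method), "exact")
})

test_that("Kabsch superposition is exact on itself and on rotated copies", {
  set.seed(10)
  P <- matrix(stats::rnorm(24, sd = 4), ncol = 3)
  expect_equal(kabsch_superpose(P, P)$rmsd, 0, tolerance = 1e-9)
  for (i in 1:5) {
    R <- random_rotation()
    Q <- P %*% R + matrix(stats::rnorm(3), nrow(P), 3, byrow = TRUE)
    expect_lt(kabsch_superpose(P, Q)$rmsd, 1e-6)
  }
  # two distinct conformers: RMSD equals the independent quaternion oracle
  for (i in 1:5) {
    Q <- P + matrix(stats::rnorm(24, sd = 0.7), ncol = 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd_oracle(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("motif superposition builds the all-vs-all RMSD matrix", {
  spec <- synthetic_cohort_spec(43, "II", n_chains = 6, m1_fraction = 1)
  dirc <- withr::local_tempdir()
  coh <- generate_cohort(spec, dirc)
  msa <- read_msa(coh$paths$msa)
  ren <- lapply(coh$toys, function(t)
    renumber_chain(t$chain, build_renumber_map(t$chain, msa)))
  motif <- motif_definitions()$ArginineTweezers
  sup <- superpose_motifs(ren, motif)
  expect_true(isSymmetric(sup$rmsd))
  expect_true(all(diag(sup$rmsd) == 0))
  expect_true(all(sup$rmsd >= 0))
  expect_equal(sup$mean_rmsd, mean(sup$rmsd[upper.tri(sup$rmsd)]))
  # a rigidly moved copy of the same motif superposes to zero
  moved <- transform_chain(ren[[1]], random_rotation(), c(5, -3, 9))
  sup2 <- superpose_motifs(list(ren[[1]], moved), motif)
  expect_lt(sup2$rmsd[1, 2], 1e-6)
})

test_that("planted geometric means are recovered within 3 standard errors", {
  spec <- synthetic_cohort_spec(44, "II", n_chains = 60, m1_fraction = 1)
  dirc <- withr::local_tempdir()
  coh <- generate_cohort(spec, dirc)
  msa <- read_msa(coh$paths$msa)
  motif <- motif_definitions()$ArginineTweezers
  obs <- do.call(rbind, lapply(coh$toys, function(t) {
    ren <- renumber_chain(t$chain, build_renumber_map(t$chain, msa))
    motif_observation(ren, motif, t$truth$binding_mode)
  }))
  g <- spec$geometry$M1
  se_d <- g$d_sd / sqrt(nrow(obs))
  se_t <- g$theta_sd / sqrt(nrow(obs))
  expect_lt(abs(mean(obs$ca_distance) - g$d_mean), 3 * se_d)
  expect_lt(abs(mean(obs$theta) - g$theta_mean), 3 * se_t)
  # per-chain values equal the planted truth exactly
  truth <- coh$truth_chains[coh$truth_chains$mapped, ]
  expect_equal(obs$ca_distance,
               truth$ca_distance[match(obs$structure_id,
                                       truth$structure_id)],
               tolerance = 1e-6)
})
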