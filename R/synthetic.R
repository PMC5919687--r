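# Synthetic-data generator: self-contained structure / MSA / CDS fixtures
# with known ground truth for every pipeline stage. Toy chains carry two
# motif residues at a planted alpha-carbon distance and side-chain angle; M1
# chains additionally carry an adenosine-phosphate-like ligand placed so that
# a planted interaction inventory (and nothing else) fires.

CYCLE_AA <- c("K", "T", "P", "V")
CYCLE_CODON <- c(K = "AAA", T = "ACT", P = "CCG", V = "GTT")
DEFAULT_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAG",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTG", K = "AAG",
  M = "ATG", F = "TTT", P = "CCG", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT")
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE), AA_THREE_TO_ONE)

# Background 40-mers; "." marks diverse (4-cycled) columns; motif residues at
# chain positions 12 and 27. The Class II design mirrors the biological
# layout: invariant arginines, a glutamate two columns downstream of the
# N-terminal tweezers residue, a conserved proline facing it on Class I.
SYN_BACKGROUND <- list(
  I = list(letters = strsplit("MKEATLGSDGALPIG.SLQHGKATVEVLDKGNWFSTAYEK", "")[[1]],
           cycle = 16L, motif_names = c("LEU", "VAL")),
  II = list(letters = strsplit("M.VA.LVGP.SRKE.ADGSTNQHEYFRGIKLVDEMNSTWA", "")[[1]],
            cycle = c(2L, 5L, 10L, 15L), motif_names = c("ARG", "ARG"))
)
SYN_CODON_OVERRIDE <- list(I = c(), II = c("11" = "AGT"))
SYN_MOTIF_POS <- c(12L, 27L)

# Paper-condition geometry defaults (Angstrom / degrees) per class and mode.
SYN_GEOMETRY_DEFAULTS <- list(
  I = list(M1 = list(d_mean = 17.92, d_sd = 0.86,
                     theta_mean = 144.90, theta_sd = 20.93),
           M2 = list(d_mean = 18.41, d_sd = 0.82,
                     theta_mean = 141.40, theta_sd = 20.13)),
  II = list(M1 = list(d_mean = 14.76, d_sd = 0.66,
                      theta_mean = 91.82, theta_sd = 8.69),
            M2 = list(d_mean = 14.93, d_sd = 0.79,
                      theta_mean = 79.81, theta_sd = 21.67))
)
SYN_MAPPED_DEFAULTS <- c(I = 441 / 448, II = 482 / 524)

#' MSA column of a toy-chain position
#'
#' The synthetic alignments place the planted motifs at the canonical
#' renumbered positions of their class (274/1361 and 698/1786).
#'
#' @param aars_class "I" or "II".
#' @param pos chain position(s) in 1..40.
#' @return MSA column(s).
#' @export
synthetic_column_of_position <- function(aars_class, pos) {
  if (aars_class == "I") ifelse(pos <= 26, 262L + pos, 1334L + pos)
  else ifelse(pos <= 26, 686L + pos, 1759L + pos)
}

synthetic_msa_width <- function(aars_class) {
  if (aars_class == "I") 1400L else 1800L
}

#' Specification of a synthetic cohort
#'
#' Defaults are the study conditions: planted distance/angle distributions
#' per binding mode follow the reported class means, and the fraction of
#' chains with both motif positions mapped follows the reported mapping
#' rates (441/448 for Class I, 482/524 for Class II).
#'
#' @param seed integer seed; all randomness derives from it.
#' @param aars_class "I" (Backbone Brackets cohort) or "II" (Arginine
#'   Tweezers cohort).
#' @param n_chains cohort size.
#' @param m1_fraction fraction of chains in binding mode M1 (exact count).
#' @param geometry list(M1 = list(d_mean, d_sd, theta_mean, theta_sd),
#'   M2 = ...); defaults per class.
#' @param mapped_fraction fraction of chains with both motif residues
#'   resolved (exact count); default per class.
#' @param m2_aa_ligand_fraction fraction of M2 chains carrying a free
#'   amino-acid ligand (the rest are apo).
#' @param n_mutations background substitutions per chain (outside the motif
#'   and codon-design windows).
#' @param coord_jitter isotropic Gaussian coordinate noise sd (Angstrom,
#'   default 0).
#' @param glycine_chains chain indices whose first motif residue is replaced
#'   by glycine (Class I only; makes theta undefined).
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_cohort_spec <- function(seed, aars_class = c("II", "I"),
                                  n_chains = 50, m1_fraction = 0.5,
                                  geometry = NULL, mapped_fraction = NULL,
                                  m2_aa_ligand_fraction = 0.25,
                                  n_mutations = 3, coord_jitter = 0,
                                  glycine_chains = integer(0)) {
  aars_class <- match.arg(aars_class)
  geometry <- geometry %||% SYN_GEOMETRY_DEFAULTS[[aars_class]]
  mapped_fraction <- mapped_fraction %||% SYN_MAPPED_DEFAULTS[[aars_class]]
  stopifnot(m1_fraction >= 0, m1_fraction <= 1,
            mapped_fraction > 0, mapped_fraction <= 1,
            all(vapply(geometry, function(g) g$d_sd >= 0 && g$theta_sd >= 0,
                       TRUE)))
  structure(list(seed = as.integer(seed), aars_class = aars_class,
                 n_chains = as.integer(n_chains),
                 m1_fraction = m1_fraction, geometry = geometry,
                 mapped_fraction = mapped_fraction,
                 m2_aa_ligand_fraction = m2_aa_ligand_fraction,
                 n_mutations = n_mutations, coord_jitter = coord_jitter,
                 glycine_chains = as.integer(glycine_chains)),
            class = "synthetic_spec")
}

synthetic_mode <- function(spec, index) {
  if (index <= round(spec$n_chains * spec$m1_fraction)) "M1" else "M2"
}

synthetic_mapped <- function(spec, index) {
  index <= round(spec$n_chains * spec$mapped_fraction)
}

# truncated-normal draw (rejection); point mass when sd == 0
draw_trunc <- function(mean, sd, lo, hi) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

# ---------------------------------------------------------------------------
# Geometry building blocks

regular_polygon_from_edge <- function(p1, p2, n, outward) {
  # 2D: full vertex list of the regular n-gon having p1->p2 as one edge,
  # built on the side indicated by the 2D unit vector `outward`.
  s <- vnorm(p2 - p1)
  mid <- (p1 + p2) / 2
  apothem <- s / (2 * tan(pi / n))
  perp <- c(-(p2 - p1)[2], (p2 - p1)[1]) / s
  if (sum(perp * outward) < 0) perp <- -perp
  ctr <- mid + apothem * perp
  a0 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
  a1 <- atan2(p2[2] - ctr[2], p2[1] - ctr[1])
  dir <- if (sin(a1 - a0) > 0) 1 else -1
  R <- s / (2 * sin(pi / n))
  t(vapply(0:(n - 1), function(k) {
    a <- a0 + dir * k * 2 * pi / n
    ctr + R * c(cos(a), sin(a))
  }, c(0, 0)))
}

# Idealized adenine in a local 2D frame: N9 at the origin, N1 on the +x axis.
adenine_template <- function() {
  ang <- c(N1 = 90, C2 = 150, N3 = 210, C4 = 270, C5 = 330, C6 = 30) * pi / 180
  hex <- t(vapply(ang, function(a) 1.39 * c(cos(a), sin(a)), c(0, 0)))
  pent <- regular_polygon_from_edge(hex["C4", ], hex["C5", ], 5,
                                    outward = unitv(
                                      (hex["C4", ] + hex["C5", ]) / 2))
  # polygon vertices walk C4 -> C5 -> around: C4, C5, N7, C8, N9
  rownames(pent) <- c("C4", "C5", "N7", "C8", "N9")
  n6 <- hex["C6", ] + 1.34 * unitv(hex["C6", ])
  atoms <- rbind(hex, pent[c("N9", "C8", "N7"), ], N6 = n6)
  # shift N9 to origin, rotate N1 onto +x
  atoms <- sweep(atoms, 2, atoms["N9", ])
  th <- atan2(atoms["N1", 2], atoms["N1", 1])
  Rm <- matrix(c(cos(-th), -sin(-th), sin(-th), cos(-th)), 2, 2, byrow = TRUE)
  atoms <- atoms %*% t(Rm)
  list(xy = atoms,
       elements = stats::setNames(substr(rownames(atoms), 1, 1),
                                  rownames(atoms)),
       n1_dist = vnorm(atoms["N1", ]),
       centroid = colMeans(atoms[rownames(atoms) != "N6", ]))
}

# place a 2D template into 3D: world = origin + x*ex + y*ey
place_2d <- function(xy, origin, ex, ey) {
  t(apply(xy, 1, function(p) origin + p[1] * ex + p[2] * ey))
}

pentagon_through_two <- function(p1, p4, normal, offset_dir) {
  # 3D regular pentagon with vertices v1..v5 (order v1,v2,v3,v4,v5) such that
  # v1 = p1 and v4 = p4 (two steps apart via v5), lying in the plane through
  # p1, p4 with the given normal; the free vertices bulge toward offset_dir.
  chord <- vnorm(p4 - p1)            # central angle 144 degrees
  R <- chord / (2 * sin(72 * pi / 180))
  ex <- unitv(p4 - p1)
  ez <- unitv(normal - sum(normal * ex) * ex)
  ey <- unitv(pracma_cross(ez, ex))
  if (sum(ey * offset_dir) < 0) ey <- -ey
  h <- sqrt(max(R^2 - (chord / 2)^2, 0))
  ctr <- (p1 + p4) / 2 + h * ey
  a1 <- atan2(sum((p1 - ctr) * ey), sum((p1 - ctr) * ex))
  # v4 is at a1 - 144deg going v1 -> v5 -> v4; so step v1->v2 is +72deg
  vert <- lapply(0:4, function(k) {
    a <- a1 + k * 72 * pi / 180
    ctr + R * (cos(a) * ex + sin(a) * ey)
  })
  # ensure v4 really lands on p4 (otherwise flip direction)
  if (vnorm(vert[[4]] - p4) > 1e-6) {
    vert <- lapply(0:4, function(k) {
      a <- a1 - k * 72 * pi / 180
      ctr + R * (cos(a) * ex + sin(a) * ey)
    })
  }
  vert
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# collinear chain + ribose pentagon + adenine from a phosphate start point
# toward an N9 target; all ideal lengths scaled uniformly by the available
# span. Returns a data.frame of named atoms (without the adenine).
ribose_chain_atoms <- function(P, N9, pent_offset_dir) {
  e <- unitv(N9 - P)
  span <- vnorm(N9 - P)
  total <- 1.6 + 1.4 + 1.5 + 2.35 + 1.47
  s <- span / total
  if (s < 0.62 || s > 1.25)
    stop("infeasible ligand placement: ribose span out of range")
  at <- list()
  at[["O5'"]] <- P + 1.6 * s * e
  at[["C5'"]] <- P + (1.6 + 1.4) * s * e
  at[["C4'"]] <- P + (1.6 + 1.4 + 1.5) * s * e
  c1 <- P + (1.6 + 1.4 + 1.5 + 2.35) * s * e
  pent <- pentagon_through_two(c1, at[["C4'"]], normal = pent_offset_dir,
                               offset_dir = pent_offset_dir)
  at[["C1'"]] <- pent[[1]]
  at[["C2'"]] <- pent[[2]]
  at[["C3'"]] <- pent[[3]]
  at[["O4'"]] <- pent[[5]]
  at
}

atoms_df <- function(named_coords, elements = NULL) {
  nm <- names(named_coords)
  xyz <- do.call(rbind, named_coords)
  if (is.null(elements)) elements <- vapply(nm, guess_element, "")
  atom_table(nm, elements, xyz[, 1], xyz[, 2], xyz[, 3])
}

# Backbone Brackets M1 ligand: ATP-like triphosphate spanning the two
# backbone amide nitrogens; the contact oxygen sits 2.9 A above N of residue
# A, ring nitrogen N1 2.9 A above N of residue B, the ring perpendicular to
# the ligand axis plane.
build_brackets_ligand <- function(d) {
  tmpl <- adenine_template()
  o1 <- c(0, 4.3, 0)
  span <- d - tmpl$n1_dist                      # contact O -> N9
  ribose_total <- 1.6 + 1.4 + 1.5 + 2.35 + 1.47
  # mono-, di- or triphosphate, whichever keeps the bond scale closest to
  # ideal (uniform compression below ~0.84 creates spurious ring chords)
  pnames <- list(c("PA"), c("PA", "OAB", "PB"),
                 c("PA", "OAB", "PB", "OBG", "PG"))
  best <- NULL
  for (np in 1:3) {
    seg <- c(1.5, rep(1.6, 2 * (np - 1)))
    s <- span / (sum(seg) + ribose_total)
    if (s >= 0.84 && s <= 1.2 &&
        (is.null(best) || abs(s - 1) < abs(best$s - 1)))
      best <- list(np = np, seg = seg, s = s)
  }
  if (is.null(best))
    stop("infeasible ligand placement: planted distance out of ligand reach")
  s <- best$s
  ex <- c(1, 0, 0)
  pos <- cumsum(c(0, best$seg)) * s
  at <- c(list(OC = o1),
          stats::setNames(lapply(seq_along(best$seg), function(i)
            o1 + pos[i + 1] * ex), pnames[[best$np]]))
  up1 <- 1.5 * s * c(0, 0.77, 0.64)
  up2 <- 1.5 * s * c(0, 0.77, -0.64)
  for (p in pnames[[best$np]][c(TRUE, FALSE)]) {
    at[[paste0("O1", substr(p, 2, 2))]] <- at[[p]] + up1
    at[[paste0("O2", substr(p, 2, 2))]] <- at[[p]] + up2
  }
  n9 <- o1 + span * ex
  last_p <- pnames[[best$np]][2 * best$np - 1]
  at <- c(at, ribose_chain_atoms(at[[last_p]], n9,
                                 pent_offset_dir = c(0, 1, 0)))
  ade <- place_2d(tmpl$xy, origin = n9, ex = ex, ey = c(0, 0, 1))
  for (k in rownames(ade)) at[[k]] <- ade[k, ]
  elements <- vapply(names(at), guess_element, "")
  new_ligand("XAT", atoms_df(at, elements), number = 201L)
}

# Arginine Tweezers M1 ligand: AMP-like; phosphate centroid ~4 A from the
# guanidinium of residue A (salt bridge), fused-ring centroid 5.6 A along +z
# from the guanidinium of residue B (perpendicular pi-cation geometry).
# Candidate phosphate directions are verified against the interaction rules
# so that nothing beyond the planted inventory can fire.
build_tweezers_ligand <- function(gA, gB, protein, ganA_idx) {
  tmpl <- adenine_template()
  dirA <- gA - gB; dirA[3] <- 0
  dirA <- unitv(dirA)
  # ring placement for a given anchor tilt toward the partner arginine:
  # fused-ring centroid 5.6 A from gB, plane horizontal, N9 toward A
  place_ring <- function(tilt) {
    cR <- gB + 5.6 * unitv(c(0, 0, 1) + tilt * dirA)
    v <- -tmpl$centroid               # template centroid -> N9 (2D)
    rot <- atan2(dirA[2], dirA[1]) - atan2(v[2], v[1])
    Rm <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2,
                 byrow = TRUE)
    xy <- sweep(tmpl$xy, 2, tmpl$centroid) %*% t(Rm)
    place_2d(xy, origin = cR, ex = c(1, 0, 0), ey = c(0, 1, 0))
  }

  pxyz <- as.matrix(protein[, c("x", "y", "z")])
  p_no <- protein$element %in% c("N", "O")
  p_c <- protein$element == "C"
  mindist <- function(points, mask) {
    if (!any(mask)) return(Inf)
    m <- pxyz[mask, , drop = FALSE]
    min(apply(points, 1, function(p) min(sqrt(colSums((t(m) - p)^2)))))
  }
  build_at <- function(P, n9, ade) {
    e <- unitv(n9 - P)
    q <- pracma_cross(e, c(0, 0, 1))
    if (vnorm(q) < 1e-6) q <- pracma_cross(e, c(0, 1, 0))
    q <- unitv(q)
    q2 <- unitv(pracma_cross(e, q))
    at <- list(P = P, O1P = P - 1.5 * e,
               O2P = P + 1.5 * (0.77 * q + 0.64 * q2),
               O3P = P + 1.5 * (0.77 * q - 0.64 * q2))
    at <- c(at, ribose_chain_atoms(P, n9, pent_offset_dir = q2))
    for (k in rownames(ade)) at[[k]] <- ade[k, ]
    at
  }
  phos_names <- c("P", "O1P", "O2P", "O3P", "O5'")
  verify <- function(at) {
    nm <- names(at)
    xyz <- do.call(rbind, at)
    el <- vapply(nm, guess_element, "")
    is_phos <- nm %in% phos_names
    lig_no_other <- xyz[!is_phos & el %in% c("N", "O"), , drop = FALSE]
    lig_c <- xyz[el == "C", , drop = FALSE]
    phos <- xyz[is_phos, , drop = FALSE]
    # no hydrogen-bond-capable pair outside the planted records
    m1 <- mindist(lig_no_other, p_no)
    # no apolar carbon pair within hydrophobic range
    m2 <- mindist(lig_c, p_c)
    # phosphate may approach only the salt-bridged guanidinium
    m3 <- mindist(phos, p_no & !ganA_idx)
    min(m1 - 4.3, m2 - 4.2, m3 - 4.3)
  }

  golden <- pi * (3 - sqrt(5))
  best <- NULL
  for (tilt in c(0, 0.25, 0.5)) {
    ade <- place_ring(tilt)
    n9 <- ade["N9", ]
    for (radius in c(4.0, 4.6, 5.2)) {
      for (k in 0:199) {
        z <- 1 - 2 * (k + 0.5) / 200
        r <- sqrt(max(1 - z^2, 0))
        w <- c(r * cos(golden * k), r * sin(golden * k), z)
        P <- gA + radius * w
        span <- vnorm(n9 - P)
        if (span < 7.0 || span > 9.9) next  # keep bond scale near ideal
        at <- tryCatch(build_at(P, n9, ade), error = function(e) NULL)
        if (is.null(at)) next
        margin <- verify(at)
        if (is.null(best) || margin > best$margin)
          best <- list(at = at, margin = margin)
      }
      if (!is.null(best) && best$margin > 0.3) break
    }
    if (!is.null(best) && best$margin > 0.3) break
  }
  if (is.null(best) || best$margin < 0)
    stop("infeasible ligand placement: no phosphate position clears the chain")
  new_ligand("XAM", atoms_df(best$at), number = 201L)
}

# Free amino-acid ligand for M2 chains: a tryptophan fragment touching one
# filler residue at hydrophobic-inert geometry (no rule fires).
build_free_aa_ligand <- function(anchor_ca) {
  cb <- anchor_ca + c(0, 0, -3.95)
  at <- list(CB = cb,
             CA = cb + c(0, 0, -1.53),
             N = cb + c(-1.2, 0.8, -2.3),
             C = cb + c(1.2, -0.4, -2.3),
             O = cb + c(1.4, -1.0, -3.3),
             OXT = cb + c(2.0, 0.3, -1.8))
  new_ligand("TRP", atoms_df(at), number = 301L)
}

# ---------------------------------------------------------------------------
# Chain construction

motif_side_chain <- function(name, ca, u, q) {
  # side-chain carbon chain along u; the most distant carbon lies exactly on
  # u, so the planted side-chain vector is recovered exactly.
  switch(name,
    ARG = list(CB = ca + 1.53 * u, CG = ca + 2.55 * u, CD = ca + 3.5 * u,
               NE = ca + 3.6 * u + 0.85 * q, CZ = ca + 4.2 * u,
               NH1 = ca + 4.2 * u + 1.33 * (0.5 * u + 0.866 * q),
               NH2 = ca + 4.2 * u + 1.33 * (0.5 * u - 0.866 * q)),
    LEU = list(CB = ca + 1.53 * u, CG = ca + 2.6 * u, CD1 = ca + 3.9 * u,
               CD2 = ca + 2.6 * u + 1.2 * q),
    VAL = list(CB = ca + 1.53 * u, CG1 = ca + 2.9 * u,
               CG2 = ca + 1.53 * u + 1.2 * q),
    GLY = list(),
    list(CB = ca + 1.53 * u))
}

guanidinium_centroid <- function(atoms) {
  colMeans(do.call(rbind, atoms[c("CZ", "NE", "NH1", "NH2")]))
}

#' Generate one toy structure with ground truth
#'
#' Builds a 40-residue chain (two motif residues with full planted side
#' chains and backbone, glycine-like filler backbones elsewhere) whose
#' alpha-carbon distance and side-chain angle equal values drawn from the
#' spec's planted distributions; M1 chains carry an adenosine-phosphate-like
#' ligand placed to satisfy the planted interaction inventory. Deterministic
#' under the spec seed.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @param index chain index in 1..n_chains.
#' @return list with \code{chain} (a \code{\link{structure_chain}}),
#'   \code{letters}, \code{present} (which of the 40 positions are resolved),
#'   and \code{truth} (mode, d, theta, mapped, inventory data.frame).
#' @export
generate_toy_structure <- function(spec, index) {
  set.seed(spec$seed * 1000L + index)
  mode <- synthetic_mode(spec, index)
  mapped <- synthetic_mapped(spec, index)
  g <- spec$geometry[[mode]]
  d <- draw_trunc(g$d_mean, g$d_sd, 10, 26)
  theta <- draw_trunc(g$theta_mean, g$theta_sd, 5, 175)

  bg <- SYN_BACKGROUND[[spec$aars_class]]
  letters1 <- bg$letters
  letters1[bg$cycle] <- CYCLE_AA[(index - 1) %% 4 + 1]
  motif_names <- bg$motif_names
  if (index %in% spec$glycine_chains && spec$aars_class == "I") {
    motif_names[1] <- "GLY"
    letters1[SYN_MOTIF_POS[1]] <- "G"
  }
  window <- if (spec$aars_class == "I") 10:23 else 2:15
  allowed <- setdiff(seq_len(40), c(window, SYN_MOTIF_POS, bg$cycle))
  mut <- sort(sample(allowed, spec$n_mutations))
  for (p in mut) {
    letters1[p] <- sample(setdiff(names(AA_ONE_TO_THREE), letters1[p]), 1)
  }

  # geometry frame
  half <- theta * pi / 360
  inward <- spec$aars_class == "II"   # tweezers point side chains inward
  ys <- if (inward) cos(half) else -cos(half)
  u1 <- c(sin(half), ys, 0)
  u2 <- c(-sin(half), ys, 0)
  caA <- c(0, 0, 0); caB <- c(d, 0, 0)
  q <- c(0, 0, 1)

  backbone <- function(ca, n_up) {
    ny <- if (n_up) c(0, 1.4, 0) else c(-0.6, -1.25, 0)
    list(N = ca + ny, C = ca + c(1.2, -0.8, 0), O = ca + c(1.2, -2.03, 0))
  }
  n_up <- spec$aars_class == "I"   # brackets: amide N points at the ligand
  bbA <- backbone(caA, n_up); bbB <- backbone(caB, n_up)
  scA <- motif_side_chain(motif_names[1], caA, u1, q)
  scB <- motif_side_chain(motif_names[2], caB, u2, q)

  res_list <- list()
  present <- rep(TRUE, 40)
  if (!mapped) present[SYN_MOTIF_POS[2]] <- FALSE
  filler_x <- seq(-10, d + 10, length.out = 40)
  for (i in which(present)) {
    if (i == SYN_MOTIF_POS[1]) {
      coords <- c(list(N = bbA$N, CA = caA, C = bbA$C, O = bbA$O), scA)
      name3 <- motif_names[1]
    } else if (i == SYN_MOTIF_POS[2]) {
      coords <- c(list(N = bbB$N, CA = caB, C = bbB$C, O = bbB$O), scB)
      name3 <- motif_names[2]
    } else {
      ca <- c(filler_x[i], -9, -7)
      coords <- list(N = ca + c(-1.2, 0.8, 0), CA = ca,
                     C = ca + c(1.2, 0.8, 0), O = ca + c(1.2, 2.03, 0))
      name3 <- AA_ONE_TO_THREE[[letters1[i]]]
    }
    res_list[[length(res_list) + 1]] <-
      new_residue(i, name3, atoms_df(coords))
  }

  ligands <- list()
  inventory <- data.frame(position = integer(0), kind = character(0),
                          fragment = character(0), backbone = logical(0))
  if (mode == "M1") {
    if (spec$aars_class == "I") {
      ligands <- list(build_brackets_ligand(d))
      inventory <- data.frame(
        position = SYN_MOTIF_POS,
        kind = "hydrogen_bond",
        fragment = c("phosphate", "adenine"),
        backbone = TRUE, stringsAsFactors = FALSE)
    } else {
      gA <- guanidinium_centroid(scA)
      gB <- guanidinium_centroid(scB)
      prot <- do.call(rbind, lapply(res_list, function(r)
        cbind(r$atoms, resno = r$number)))
      ganA_idx <- prot$resno == SYN_MOTIF_POS[1] &
        prot$name %in% c("CZ", "NE", "NH1", "NH2")
      ligands <- list(build_tweezers_ligand(gA, gB, prot, ganA_idx))
      inventory <- data.frame(
        position = SYN_MOTIF_POS,
        kind = c("salt_bridge", "pi_cation"),
        fragment = c("phosphate", "adenine"),
        backbone = FALSE, stringsAsFactors = FALSE)
    }
  } else if (mode == "M2" && spec$m2_aa_ligand_fraction > 0) {
    m2_index <- index - round(spec$n_chains * spec$m1_fraction)
    n_m2 <- spec$n_chains - round(spec$n_chains * spec$m1_fraction)
    if (m2_index >= 1 && m2_index <= ceiling(n_m2 * spec$m2_aa_ligand_fraction))
      ligands <- list(build_free_aa_ligand(c(filler_x[5], -9, -7)))
  }

  chain <- structure_chain(sprintf("z%04d", index), "A", res_list, ligands)
  if (spec$coord_jitter > 0) {
    jit <- function(atoms) {
      n <- nrow(atoms)
      atoms$x <- atoms$x + stats::rnorm(n, 0, spec$coord_jitter)
      atoms$y <- atoms$y + stats::rnorm(n, 0, spec$coord_jitter)
      atoms$z <- atoms$z + stats::rnorm(n, 0, spec$coord_jitter)
      atoms
    }
    chain$residues <- lapply(chain$residues, function(r) {
      r$atoms <- jit(r$atoms); r })
    chain$ligands <- lapply(chain$ligands, function(l) {
      l$atoms <- jit(l$atoms); l })
  }
  glycine <- motif_names[1] == "GLY"
  list(chain = chain, letters = letters1, present = present,
       truth = list(structure_id = chain$structure_id, binding_mode = mode,
                    ca_distance = d,
                    theta = if (glycine) NA_real_ else theta,
                    mapped = mapped, inventory = inventory,
                    has_aa_ligand = length(ligands) > 0 && mode == "M2"))
}

# ---------------------------------------------------------------------------
# MSA / CDS generation

synthetic_codon <- function(aars_class, pos, letter) {
  bg <- SYN_BACKGROUND[[aars_class]]
  ov <- SYN_CODON_OVERRIDE[[aars_class]]
  if (pos %in% bg$cycle) return(CYCLE_CODON[[letter]] %||% DEFAULT_CODON[[letter]])
  if (as.character(pos) %in% names(ov)) return(ov[[as.character(pos)]])
  DEFAULT_CODON[[letter]]
}

#' Generate the cohort MSA, coding sequences and codon ground truth
#'
#' MSA rows equal the toy chains' sequences placed on the fixed synthetic
#' column layout (motifs at the canonical renumbered positions); coding
#' sequences translate exactly to the protein rows. The designed codon
#' windows (Class I columns 272-285, Class II columns 688-701) yield a
#' deterministic consensus and a known antisense pairing, returned as
#' ground truth.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @param toys list of results of \code{\link{generate_toy_structure}};
#'   generated if NULL.
#' @return list with \code{msa_rows} (named gapped strings), \code{cds}
#'   (named DNA strings), \code{width}, \code{expected_consensus}
#'   (data.frame msa_column, consensus), and for Class II vs a paired Class I
#'   design the caller combines cohorts; see \code{\link{synthetic_pairing_truth}}.
#' @export
generate_msa_and_cds <- function(spec, toys = NULL) {
  if (is.null(toys))
    toys <- lapply(seq_len(spec$n_chains), generate_toy_structure,
                   spec = spec)
  width <- synthetic_msa_width(spec$aars_class)
  rows <- character(0); cds <- character(0)
  for (t in toys) {
    chars <- rep("-", width)
    idx <- which(t$present)
    chars[synthetic_column_of_position(spec$aars_class, idx)] <-
      t$letters[idx]
    rows[t$truth$structure_id] <- paste(chars, collapse = "")
    codons <- vapply(idx, function(p)
      synthetic_codon(spec$aars_class, p, t$letters[p]), "")
    cds[t$truth$structure_id] <- paste(codons, collapse = "")
  }
  window <- if (spec$aars_class == "I") 272:285 else 688:701
  pos_of_col <- function(col) {
    if (spec$aars_class == "I") col - 262L else col - 686L
  }
  expected <- do.call(rbind, lapply(window, function(col) {
    p <- pos_of_col(col)
    cods <- vapply(seq_along(toys), function(i)
      synthetic_codon(spec$aars_class, p, toys[[i]]$letters[p]), "")
    cc <- consensus_codon(cods)
    data.frame(msa_column = col, consensus = cc$bases,
               occupancy = cc$occupancy, stringsAsFactors = FALSE)
  }))
  list(msa_rows = rows, cds = cds, width = width,
       expected_consensus = expected)
}

#' Ground-truth antisense pairing of two synthetic cohorts
#'
#' Pairs the designed Class I window (columns 272-285) against the designed
#' Class II window (columns 701-688, antiparallel) using the generators'
#' expected consensus codons.
#'
#' @param truth_I,truth_II results of \code{\link{generate_msa_and_cds}} for
#'   a Class I and a Class II spec.
#' @return an \code{aars_pairing} object (the planted truth).
#' @export
synthetic_pairing_truth <- function(truth_I, truth_II) {
  cI <- truth_I$expected_consensus
  cI <- cI[order(cI$msa_column), ]
  cII <- truth_II$expected_consensus
  cII <- cII[order(-cII$msa_column), ]
  antisense_pairing(
    data.frame(msa_column = cI$msa_column, consensus = cI$consensus),
    data.frame(msa_column = cII$msa_column, consensus = cII$consensus),
    classII_reversed = FALSE)
}

#' Write a complete synthetic cohort to disk
#'
#' Emits one PDB file per chain under \code{dir/structures}, the MSA and CDS
#' FASTA files, an annotation TSV and the chain-level truth table. All
#' outputs are deterministic under the spec seed.
#'
#' @param spec a \code{\link{synthetic_cohort_spec}}.
#' @param dir output directory (created if needed).
#' @return list with \code{toys}, \code{seqdata}
#'   (\code{\link{generate_msa_and_cds}} result), \code{annotations},
#'   \code{truth_chains} and the file \code{paths}.
#' @export
generate_cohort <- function(spec, dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  toys <- lapply(seq_len(spec$n_chains), generate_toy_structure, spec = spec)
  paths <- list(structures = file.path(dir, "structures"),
                msa = file.path(dir, "msa.fasta"),
                cds = file.path(dir, "cds.fasta"),
                annotations = file.path(dir, "annotations.tsv"),
                truth = file.path(dir, "truth_chains.tsv"))
  for (t in toys)
    write_structure(t$chain, file.path(paths$structures,
                                       paste0(t$truth$structure_id, "_A.pdb")))
  seqdata <- generate_msa_and_cds(spec, toys)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqdata$msa_rows), paths$msa)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqdata$cds), paths$cds)

  types <- AARS_CLASS_TYPES[[spec$aars_class]]
  kingdoms <- c("bacteria", "eukaryota", "archaea")
  ann <- data.frame(
    pdb_id = vapply(toys, function(t) t$truth$structure_id, ""),
    chain = "A", class = spec$aars_class,
    type = types[(seq_len(spec$n_chains) - 1) %% length(types) + 1],
    superkingdom = kingdoms[(seq_len(spec$n_chains) - 1) %% 3 + 1],
    taxid = 1000L + seq_len(spec$n_chains),
    mutant = FALSE,
    resolution = 1.5 + (seq_len(spec$n_chains) %% 10) / 10,
    stringsAsFactors = FALSE)
  utils::write.table(ann, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- do.call(rbind, lapply(toys, function(t)
    data.frame(structure_id = t$truth$structure_id,
               binding_mode = t$truth$binding_mode,
               ca_distance = t$truth$ca_distance, theta = t$truth$theta,
               mapped = t$truth$mapped,
               n_planted_interactions = nrow(t$truth$inventory),
               stringsAsFactors = FALSE)))
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(toys = toys, seqdata = seqdata, annotations = ann,
       truth_chains = truth, paths = paths)
}
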