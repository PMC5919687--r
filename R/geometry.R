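# Geometric descriptors of motif occurrences: alpha-carbon distance,
# side-chain angle theta, binding-mode statistics and backbone superposition.

#' Alpha-carbon distance between two residues
#'
#' @param res_a,res_b residues exposing a CA atom.
#' @return Euclidean CA-CA distance in Angstrom, or \code{NA_real_} with a
#'   message if a CA atom is missing.
#' @export
ca_distance <- function(res_a, res_b) {
  a <- residue_atom(res_a, "CA")
  b <- residue_atom(res_b, "CA")
  if (is.null(a) || is.null(b)) {
    message("missing CA atom; alpha-carbon distance undefined")
    return(NA_real_)
  }
  vnorm(a - b)
}

#' Side-chain vector of a residue
#'
#' The side chain is abstracted as the vector from the alpha carbon to the
#' most distant side-chain carbon atom (backbone C and CA excluded; ties are
#' broken toward the lexicographically smallest atom name). Undefined for
#' glycine and for residues without a resolved side-chain carbon.
#'
#' @param residue a residue with a CA atom.
#' @return numeric 3-vector, or \code{NULL} when undefined.
#' @export
side_chain_vector <- function(residue) {
  if (residue$name == "GLY") return(NULL)
  ca <- residue_atom(residue, "CA")
  if (is.null(ca)) return(NULL)
  at <- residue$atoms
  cand <- which(at$element == "C" & !(at$name %in% c("CA", "C")))
  if (length(cand) == 0) return(NULL)
  d <- vapply(cand, function(i)
    vnorm(as.numeric(at[i, c("x", "y", "z")]) - ca), 0)
  best <- cand[order(-d, at$name[cand])][1]
  v <- as.numeric(at[best, c("x", "y", "z")]) - ca
  if (vnorm(v) < 1e-9) return(NULL)
  v
}

#' Side-chain angle theta between two residues
#'
#' Angle between the two side-chain vectors, in \code{[0, 180]} degrees;
#' 0 or 180 degrees means parallel side chains. Undefined (NA) if either
#' side-chain vector is undefined (e.g. glycine).
#'
#' @param res_a,res_b residues.
#' @return degrees, or \code{NA_real_}.
#' @export
side_chain_angle <- function(res_a, res_b) {
  va <- side_chain_vector(res_a)
  vb <- side_chain_vector(res_b)
  if (is.null(va) || is.null(vb)) return(NA_real_)
  angle_between(va, vb)
}

#' Build a motif observation
#'
#' @param chain renumbered chain containing the motif.
#' @param motif a motif definition (see \code{\link{motif_definitions}}).
#' @param binding_mode "M1" or "M2".
#' @return one-row data.frame (structure_id, chain_id, motif, position_a,
#'   position_b, ca_distance, theta, binding_mode) or NULL when the motif is
#'   not mapped in this chain.
#' @export
motif_observation <- function(chain, motif, binding_mode) {
  loc <- locate_motif(chain, motif)
  if (!loc$found) return(NULL)
  d <- ca_distance(loc$residues[[1]], loc$residues[[2]])
  stopifnot(is.na(d) || d > 0)
  data.frame(structure_id = chain$structure_id, chain_id = chain$chain_id,
             motif = motif$name, position_a = motif$positions[1],
             position_b = motif$positions[2], ca_distance = d,
             theta = side_chain_angle(loc$residues[[1]], loc$residues[[2]]),
             binding_mode = binding_mode, stringsAsFactors = FALSE)
}

#' Mann-Whitney U test (two-sided)
#'
#' U is computed by direct pairwise comparison (ties count 1/2). For small
#' samples (pooled n <= \code{exact_max}) the two-sided p-value is obtained
#' by exact enumeration of all group assignments of the pooled values, which
#' remains valid under ties; otherwise the tie-corrected normal approximation
#' with continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest pooled sample size for exact enumeration.
#' @return list with \code{U} (statistic for x), \code{p} and
#'   \code{method} ("exact" or "normal").
#' @export
mann_whitney_u <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1)
  ustat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  U <- ustat(x, y)
  N <- n1 + n2
  if (N <= exact_max) {
    pool <- c(x, y)
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, function(idx) ustat(pool[idx], pool[-idx]))
    mu <- n1 * n2 / 2
    p <- min(1, sum(abs(us - mu) >= abs(U - mu) - 1e-12) / ncol(combs))
    return(list(U = U, p = p, method = "exact"))
  }
  r <- rank(c(x, y))
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}

#' Summarize motif geometry per binding mode
#'
#' Groups observations by (motif, binding mode) and reports n, mean and
#' sample standard deviation for the alpha-carbon distance and theta
#' (undefined angles are excluded listwise from theta statistics only), plus
#' the two-sided Mann-Whitney comparison of M1 vs M2 per descriptor
#' (computed when both groups have at least 3 defined values).
#'
#' @param observations data.frame of \code{\link{motif_observation}} rows.
#' @return list with \code{groups} (data.frame of per-group statistics) and
#'   \code{tests} (data.frame of Mann-Whitney results per motif and
#'   descriptor).
#' @export
summarize_geometry <- function(observations) {
  stopifnot(nrow(observations) >= 1)
  grp <- split(observations,
               list(observations$motif, observations$binding_mode),
               drop = TRUE)
  groups <- do.call(rbind, lapply(grp, function(g) {
    th <- g$theta[!is.na(g$theta)]
    dd <- g$ca_distance[!is.na(g$ca_distance)]
    data.frame(motif = g$motif[1], binding_mode = g$binding_mode[1],
               n = nrow(g),
               n_distance = length(dd),
               distance_mean = mean(dd), distance_sd = stats::sd(dd),
               n_theta = length(th),
               theta_mean = if (length(th)) mean(th) else NA_real_,
               theta_sd = if (length(th) > 1) stats::sd(th) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL

  tests <- list()
  for (m in unique(observations$motif)) {
    sub <- observations[observations$motif == m, ]
    for (desc in c("ca_distance", "theta")) {
      v1 <- sub[[desc]][sub$binding_mode == "M1"]
      v2 <- sub[[desc]][sub$binding_mode == "M2"]
      v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
      if (length(v1) >= 3 && length(v2) >= 3) {
        mw <- mann_whitney_u(v1, v2)
        tests[[length(tests) + 1]] <- data.frame(
          motif = m, descriptor = desc, n_m1 = length(v1), n_m2 = length(v2),
          U = mw$U, p = mw$p, method = mw$method, stringsAsFactors = FALSE)
      }
    }
  }
  list(groups = groups,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(motif = character(0), descriptor = character(0)))
}

# ---------------------------------------------------------------------------
# Rigid superposition

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares superposition of two paired coordinate sets via singular
#' value decomposition of the cross-covariance matrix, with the reflection
#' guard on the determinant.
#'
#' @param P,Q n x 3 coordinate matrices (P is moved onto Q).
#' @return list with rotation \code{R}, translation \code{t} (so that
#'   \code{P \%*\% R + t} superposes onto Q) and \code{rmsd}.
#' @export
kabsch_superpose <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  moved <- P0 %*% R
  rmsd <- sqrt(mean(rowSums((moved - Q0)^2)))
  list(R = R, t = cq - as.numeric(cp %*% R), rmsd = rmsd)
}

motif_backbone_coords <- function(chain, motif,
                                  scope = c("N", "CA", "C", "O")) {
  loc <- locate_motif(chain, motif)
  if (!loc$found) return(NULL)
  coords <- lapply(loc$residues, function(r) {
    xs <- lapply(scope, function(a) residue_atom(r, a))
    if (any(vapply(xs, is.null, TRUE))) return(NULL)
    do.call(rbind, xs)
  })
  if (any(vapply(coords, is.null, TRUE))) return(NULL)
  do.call(rbind, coords)
}

#' All-vs-all backbone superposition of motif occurrences
#'
#' Superposes every pair of motif occurrences on the backbone atoms (N, CA,
#' C, O of both residues) with \code{\link{kabsch_superpose}} and reports the
#' pairwise RMSD matrix and its mean. Occurrences missing a scoped atom are
#' excluded with a message.
#'
#' @param chains list of renumbered chains.
#' @param motif motif definition.
#' @param scope backbone atom names used for the superposition.
#' @return list with \code{rmsd} (symmetric matrix), \code{mean_rmsd},
#'   \code{used} (chain keys included) and \code{excluded}.
#' @export
superpose_motifs <- function(chains, motif, scope = c("N", "CA", "C", "O")) {
  keys <- vapply(chains, function(ch)
    paste0(ch$structure_id, "_", ch$chain_id), "")
  coords <- lapply(chains, motif_backbone_coords, motif = motif,
                   scope = scope)
  ok <- !vapply(coords, is.null, TRUE)
  if (any(!ok))
    message("excluded from superposition (missing scoped atoms): ",
            paste(keys[!ok], collapse = ", "))
  coords <- coords[ok]
  keys <- keys[ok]
  n <- length(coords)
  rmsd <- matrix(0, n, n, dimnames = list(keys, keys))
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      rmsd[i, j] <- rmsd[j, i] <-
        kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  list(rmsd = rmsd,
       mean_rmsd = if (n >= 2) mean(rmsd[upper.tri(rmsd)]) else NA_real_,
       used = keys, excluded = sum(!ok))
}

#' Apply a rigid motion to a chain (testing / invariance checks)
#'
#' @param chain a \code{\link{structure_chain}}.
#' @param R 3x3 rotation matrix.
#' @param t translation 3-vector.
#' @return the transformed chain.
#' @export
transform_chain <- function(chain, R, t = c(0, 0, 0)) {
  move <- function(atoms) {
    xyz <- atom_xyz(atoms) %*% R
    atoms$x <- xyz[, 1] + t[1]
    atoms$y <- xyz[, 2] + t[2]
    atoms$z <- xyz[, 3] + t[3]
    atoms
  }
  chain$residues <- lapply(chain$residues, function(r) {
    r$atoms <- move(r$atoms); r
  })
  chain$ligands <- lapply(chain$ligands, function(l) {
    l$atoms <- move(l$atoms); l
  })
  chain
}
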