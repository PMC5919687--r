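# Independent oracles used by the tests; these deliberately avoid the code
# paths of the package implementation.

# Affine-gap global alignment by explicit three-state dynamic programming
# (gap of length L costs open + L * ext, matching the package's scoring).
# Returns the optimal score and the set of percent identities (terminal
# overhang columns excluded) over all optimal alignments (path count capped).
gotoh_oracle <- function(a, b, open = 10, ext = 0.5, max_paths = 2000) {
  submat <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- submat[A[i - 1], B[j - 1]]
    M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])

  # enumerate all optimal tracebacks (capped)
  paths <- list()
  walk <- function(i, j, state, cols) {
    if (length(paths) >= max_paths) return()
    if (i == 1 && j == 1 && state == "M") {
      paths[[length(paths) + 1]] <<- rev(cols)
      return()
    }
    tol <- 1e-9
    if (state == "M") {
      if (i > 1 && j > 1) {
        s <- submat[A[i - 1], B[j - 1]]
        for (st in c("M", "X", "Y")) {
          prev <- switch(st, M = M, X = X, Y = Y)[i - 1, j - 1]
          if (abs(M[i, j] - (s + prev)) < tol)
            walk(i - 1, j - 1, st, c(cols, paste0(A[i - 1], B[j - 1])))
        }
      }
    } else if (state == "X") {
      if (i > 1) {
        if (abs(X[i, j] - (M[i - 1, j] - open - ext)) < tol)
          walk(i - 1, j, "M", c(cols, paste0(A[i - 1], "-")))
        if (abs(X[i, j] - (X[i - 1, j] - ext)) < tol)
          walk(i - 1, j, "X", c(cols, paste0(A[i - 1], "-")))
        if (abs(X[i, j] - (Y[i - 1, j] - open - ext)) < tol)
          walk(i - 1, j, "Y", c(cols, paste0(A[i - 1], "-")))
      }
      if (i == 1 && j == 1) paths[[length(paths) + 1]] <<- rev(cols)
    } else {
      if (j > 1) {
        if (abs(Y[i, j] - (M[i, j - 1] - open - ext)) < tol)
          walk(i, j - 1, "M", c(cols, paste0("-", B[j - 1])))
        if (abs(Y[i, j] - (Y[i, j - 1] - ext)) < tol)
          walk(i, j - 1, "Y", c(cols, paste0("-", B[j - 1])))
        if (abs(Y[i, j] - (X[i, j - 1] - open - ext)) < tol)
          walk(i, j - 1, "X", c(cols, paste0("-", B[j - 1])))
      }
      if (i == 1 && j == 1) paths[[length(paths) + 1]] <<- rev(cols)
    }
  }
  for (st in c("M", "X", "Y")) {
    v <- switch(st, M = M, X = X, Y = Y)[n + 1, m + 1]
    if (abs(v - best) < 1e-9) walk(n + 1, m + 1, st, character(0))
  }
  idents <- unique(vapply(paths, function(cols) {
    ca <- substr(cols, 1, 1); cb <- substr(cols, 2, 2)
    nga <- which(ca != "-"); ngb <- which(cb != "-")
    lo <- max(min(nga), min(ngb)); hi <- min(max(nga), max(ngb))
    if (hi < lo) return(0)
    idx <- lo:hi
    100 * sum(ca[idx] == cb[idx] & ca[idx] != "-") / length(idx)
  }, 0))
  list(score = best, identities = idents)
}

# Horn's quaternion method for optimal rigid superposition RMSD.
quaternion_rmsd_oracle <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  S <- t(P0) %*% Q0
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,      -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,      -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(P0^2) + sum(Q0^2) - 2 * lmax) / nrow(P)
  sqrt(max(msd, 0))
}

# Exact two-sided Mann-Whitney p by full enumeration over group assignments,
# computed through the rank-sum route (W = R1 - n1(n1+1)/2).
mw_enumeration_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y); N <- n1 + n2
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  min(1, sum(abs(us - mu) >= abs(obs - mu) - 1e-12) / ncol(combs))
}

random_rotation <- function() {
  axis <- stats::rnorm(3)
  aarsmotifs:::rotation_matrix(axis, stats::runif(1, 0, 360))
}
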