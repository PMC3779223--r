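# Independent oracles used to validate the analytic implementations.
# They share no code path with the package internals they check.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force minimum superposition RMSD: random quaternion grid plus
# Nelder-Mead refinement of the best candidates.  The translation is always
# optimal at centroid alignment for squared loss, so only rotations are
# searched.
rmsd_oracle <- function(X, Y, n_grid = 4000, n_refine = 10, seed = 99) {
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  f <- function(q) {
    R <- quat_to_rot(q)
    sqrt(mean(rowSums((Yc %*% t(R) - Xc)^2)))
  }
  with_seed(seed, {
    qs <- matrix(stats::rnorm(4 * n_grid), ncol = 4)
    vals <- apply(qs, 1, f)
    best <- Inf
    for (i in order(vals)[seq_len(n_refine)]) {
      o <- stats::optim(qs[i, ], f, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    best
  })
}

# Exhaustive-seed TM-score oracle: every contiguous fragment of every
# length >= 4 seeds a superposition, each refined by the standard
# keep-close-pairs iteration; the maximum score over everything is
# returned.  The package's search uses only a sparse subset of these seeds.
tm_oracle <- function(X, Y, L_N, d0) {
  L <- nrow(X)
  best <- 0
  score_d2 <- function(d2) sum(1 / (1 + d2 / d0^2)) / L_N
  fit_score <- function(idx) {
    tr <- kabsch(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
    Yt <- sweep(Y %*% t(tr$rotation), 2, tr$translation, "+")
    rowSums((Yt - X)^2)
  }
  for (len in 4:L) for (s in seq_len(L - len + 1L)) {
    d2 <- fit_score(s:(s + len - 1L))
    best <- max(best, score_d2(d2))
    prev <- -1
    for (round in 1:20) {
      sel <- which(sqrt(d2) < d0 + 1)
      if (length(sel) < 4L) sel <- order(d2)[1:4]
      d2 <- fit_score(sel)
      sc <- score_d2(d2)
      best <- max(best, sc)
      if (abs(sc - prev) < 1e-6) break
      prev <- sc
    }
  }
  best
}

random_rigid <- function(seed) {
  with_seed(seed, {
    A <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(A))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    list(R = Q, t = stats::runif(3, -20, 20))
  })
}

apply_rigid <- function(xyz, rt) sweep(xyz %*% t(rt$R), 2, rt$t, "+")
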