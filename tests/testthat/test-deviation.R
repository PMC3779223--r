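make_ensemble <- function(seed, n = 6L, core = 60L, plan = list()) {
  sf <- make_superfamily(synthetic_spec(n, core, 0.3, outlier_plan = plan,
                                        seed = seed))
  sf$ensemble <- multiple_superpose(sf$alignment, sf$structures)
  sf
}

test_that("rmsd matrix is symmetric, zero-diagonal and matches a from-scratch rescan", {
  sf <- make_ensemble(41, plan = list(list(member = 2, perturbations = list(
    insertion(30, 8), deletion(10, 5)))))
  m <- rmsd_matrix(sf$alignment, sf$structures, sf$ensemble)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 6))
  expect_true(all(m >= 0))
  ## independent recomputation: re-extract matched coordinates per pair
  ids <- sf$alignment$member_ids
  for (i in 1:5) for (j in (i + 1):6) {
    cols <- which(!is.na(sf$alignment$rows[[ids[i]]]) &
                  !is.na(sf$alignment$rows[[ids[j]]]))
    xi <- sf$ensemble$superposed[[ids[i]]][sf$alignment$rows[[ids[i]]][cols], ]
    xj <- sf$ensemble$superposed[[ids[j]]][sf$alignment$rows[[ids[j]]][cols], ]
    expect_equal(m[i, j], sqrt(mean(rowSums((xi - xj)^2))), tolerance = 1e-12)
  }
})

test_that("uniform displacement in a common frame gives exactly that RMSD", {
  X <- test_trace(30, 2)
  aln <- multiple_alignment(c(a = strrep("A", 30), b = strrep("A", 30)))
  structures <- list(domain_structure("a", X),
                     domain_structure("b", sweep(X, 2, c(2, 0, 0), "+")))
  ens <- list(superposed = list(a = structures[[1]]$xyz,
                                b = structures[[2]]$xyz))
  m <- rmsd_matrix(aln, structures, ens)
  expect_equal(m["a", "b"], 2.0, tolerance = 1e-12)
  ## identical, identically-placed members give 0
  ens$superposed$b <- X
  expect_equal(rmsd_matrix(aln, structures, ens)["a", "b"], 0)
})

test_that("pairwise re-superposition mode never exceeds the common-frame values", {
  sf <- make_ensemble(43, plan = list(list(
    member = 1, perturbations = plant_two_hinge_outlier(90))), core = 90L)
  m_common <- rmsd_matrix(sf$alignment, sf$structures, sf$ensemble)
  m_repair <- rmsd_matrix(sf$alignment, sf$structures, mode = "repair")
  expect_true(all(m_repair <= m_common + 1e-9))
})

test_that("mean_rmsd averages off-diagonal entries, matching brute force", {
  m <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(unname(mean_rmsd(m)), c(3, 4, 5))
  ## 2-member superfamily: both means equal the single pairwise value
  m2 <- matrix(c(0, 1.7, 1.7, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  expect_equal(unname(mean_rmsd(m2)), c(1.7, 1.7))
  ## random symmetric matrix vs naive double loop
  r <- with_seed(9, matrix(stats::runif(100, 0, 10), 10, 10))
  r <- (r + t(r)) / 2; diag(r) <- 0
  dimnames(r) <- list(paste0("m", 1:10), paste0("m", 1:10))
  naive <- sapply(1:10, function(i) {
    acc <- 0
    for (j in 1:10) if (j != i) acc <- acc + r[i, j]
    acc / 9
  })
  expect_equal(unname(mean_rmsd(r)), naive)
})

test_that("tm_score is 1 for self-comparison and rigid-invariant", {
  sf <- make_ensemble(47, n = 3, core = 45)
  a <- sf$structures[[1]]; b <- sf$structures[[2]]
  expect_equal(tm_score(sf$alignment, a, a), 1.0, tolerance = 1e-12)
  base <- tm_score(sf$alignment, a, b)
  moved <- domain_structure("m02", apply_rigid(b$xyz, random_rigid(5)))
  expect_equal(tm_score(sf$alignment, a, moved), base, tolerance = 1e-9)
  expect_gt(base, 0); expect_lte(base, 1)
})

test_that("a configuration with all pairs at distance d0 scores exactly one half", {
  ## points on a huge circle pushed radially outward by d0: the identity
  ## superposition leaves every distance at d0 and nothing can do better
  n <- 24; radius <- 500
  ang <- 2 * pi * seq_len(n) / n
  X <- cbind(radius * cos(ang), radius * sin(ang), 0)
  d0 <- 3
  Y <- cbind((radius + d0) * cos(ang), (radius + d0) * sin(ang), 0)
  expect_equal(rebelscan:::tm_align(X, Y, n, d0), 0.5, tolerance = 1e-9)
})

test_that("tm normalization rules change the reference length as documented", {
  sf <- make_superfamily(synthetic_spec(
    3, 60, 0.2, outlier_plan = list(list(member = 2, perturbations = list(
      deletion(10, 15)))), seed = 53))
  a <- sf$structures[["m01"]]; b <- sf$structures[["m02"]]  # 60 vs 45 res
  t_short <- tm_score(sf$alignment, a, b, tm_params("shorter"))
  t_long <- tm_score(sf$alignment, a, b, tm_params("longer"))
  t_first <- tm_score(sf$alignment, a, b, tm_params("first"))
  t_second <- tm_score(sf$alignment, a, b, tm_params("second"))
  expect_equal(t_first, t_long)    # a is the longer member
  expect_equal(t_second, t_short)  # b is the shorter member
  expect_gt(t_short, t_long)       # smaller L_N can only raise the score
})

test_that("tm_score agrees with the exhaustive-seed oracle on small instances", {
  gaps <- vapply(1:6, function(i) {
    L <- with_seed(600 + i, sample(25:40, 1))
    X <- test_trace(L, 700 + i)
    Y <- if (i %% 2 == 0) {
      X + with_seed(800 + i, matrix(stats::rnorm(3 * L, sd = 1.5), ncol = 3))
    } else {
      h <- with_seed(900 + i, sample(10:(L - 8), 1))
      rebelscan:::apply_perturbation(
        X, hinge(c(h, L), 100, axis_choice = 1 + i %% 2)) +
        with_seed(950 + i, matrix(stats::rnorm(3 * L, sd = 0.3), ncol = 3))
    }
    Y <- apply_rigid(Y, random_rigid(i))
    d0 <- rebelscan:::tm_d0(L, 0.5)
    abs(rebelscan:::tm_align(X, Y, L, d0) - tm_oracle(X, Y, L, d0))
  }, numeric(1))
  expect_true(all(gaps < 1e-6))
})

test_that("outlier calls use strict AND of both thresholds", {
  mr <- c(a = 6.0, b = 3.0, c = 5.5, d = 7.0)
  tm <- c(a = 0.40, b = 0.80, c = 0.30, d = 0.60)
  cls <- classify_outliers(mr, tm)
  expect_identical(cls$outliers, "a")           # 6.0 & 0.40 -> outlier
  expect_identical(cls$category, "single-outlier")
  ## exactly at the cut is not an outlier (c: 5.5; d: TM 0.60 fails)
  expect_false("c" %in% cls$outliers)
  expect_false("d" %in% cls$outliers)
  or <- classify_outliers(mr, tm, rule = "or")
  expect_setequal(or$outliers, c("a", "c", "d"))
  expect_identical(or$category, "multiple-outlier")
  expect_identical(classify_outliers(c(a = 1, b = 1), c(a = 0.9, b = 0.9))$category,
                   "no-outlier")
  expect_identical(classify_outliers(stats::setNames(rep(6, 2), c("a", "b")),
                                     c(a = 0.1, b = 0.1))$category,
                   "two-outlier")
})

test_that("identical ensembles yield zero means and no outliers", {
  X <- test_trace(40, 3)
  ids <- paste0("m", 1:4)
  aln <- multiple_alignment(stats::setNames(rep(strrep("A", 40), 4), ids))
  structures <- lapply(ids, function(id) domain_structure(id, X))
  ens <- multiple_superpose(aln, structures)
  dev <- deviation_report(aln, structures, ens)
  expect_equal(max(dev$mean_rmsd), 0, tolerance = 1e-9)
  expect_length(dev$outliers, 0)
  expect_identical(dev$category, "no-outlier")
})

test_that("family specificity requires one outlier family absent from non-outliers", {
  fams <- c(d1ppya_ = "ADC", d1uhez1 = "ADC",
            stats::setNames(rep(c("FDH-C", "Cdc48-N"), 7),
                            paste0("d", 1:14)))
  fs <- family_specificity(c("d1ppya_", "d1uhez1"), fams)
  expect_true(fs$family_specific)
  expect_identical(fs$label, "ADC")
  ## outliers in different families
  fams2 <- c(a = "F1", b = "F2", c = "F3", d = "F3")
  expect_false(family_specificity(c("a", "b"), fams2)$family_specific)
  ## outlier family shared with a non-outlier
  expect_false(family_specificity("c", fams2)$family_specific)
  expect_error(family_specificity(character(), fams2),
               class = "rebelscan_no_outliers")
})

test_that("gap runs flag planted insertions and terminal extensions", {
  ## leading run gapped in all others -> N-terminal extension
  aln <- multiple_alignment(c(a = paste0(strrep("A", 10), strrep("B", 20)),
                              b = paste0(strrep("-", 10), strrep("B", 20)),
                              c = paste0(strrep("-", 10), strrep("B", 20))))
  runs <- gap_run_summary(aln, "a")
  expect_identical(runs$kind, "N-terminal-extension")
  expect_identical(runs$start_col, 1L)
  expect_identical(runs$length, 10L)
  ## gapless alignment -> empty
  expect_identical(nrow(gap_run_summary(multiple_alignment(
    c(a = "ABC", b = "DEF")), "a")), 0L)
  ## planted internal 12-residue insertion recovered at the exact columns
  sf <- make_superfamily(synthetic_spec(
    6, 60, 0.2, outlier_plan = list(list(member = 4, perturbations = list(
      insertion(30, 12)))), seed = 61))
  runs <- gap_run_summary(sf$alignment, "m04")
  expect_identical(runs$kind, "insertion")
  expect_identical(runs$length, 12L)
  expect_identical(runs$start_col, sf$truth$insertion_columns[["m04"]][1])
  ## a private insertion is no deletion for the others (majority still gapped)
  expect_identical(nrow(gap_run_summary(sf$alignment, "m01")), 0L)
  ## a planted deletion shows as a deletion run for its carrier
  sf_del <- make_superfamily(synthetic_spec(
    6, 60, 0.2, outlier_plan = list(list(member = 2, perturbations = list(
      deletion(20, 9)))), seed = 62))
  runs_del <- gap_run_summary(sf_del$alignment, "m02")
  expect_identical(runs_del$kind, "deletion")
  expect_identical(runs_del$length, 9L)
  expect_identical(runs_del$start_col, 20L)
})

test_that("circular permutation screen recovers planted shifts and stays silent on noise", {
  ## self comparison: shift 0, improvement 0
  a <- domain_structure("a", generate_core_backbone(120, 71))
  self <- circular_permutation_score(a, a)
  expect_identical(self$best_shift, 0L)
  expect_equal(self$improvement, 0)
  expect_false(self$signal)
  ## planted CP by 30 residues
  for (i in 1:3) {
    X <- generate_core_backbone(120, 9000 + i)
    b <- domain_structure("b", apply_rigid(
      rebelscan:::apply_perturbation(X, circular_permutation(30)) +
        with_seed(20 + i, matrix(stats::rnorm(360, sd = 0.3), ncol = 3)),
      random_rigid(i)))
    r <- circular_permutation_score(domain_structure("a", X), b)
    expect_lte(abs(r$best_shift - 30L), 4L)
    expect_true(r$signal)
  }
  ## unrelated random traces: no CP signal over 20 pairs
  signals <- vapply(1:20, function(i) {
    pa <- domain_structure("a", generate_core_backbone(60, 7000 + i))
    pb <- domain_structure("b", generate_core_backbone(60, 8000 + i))
    circular_permutation_score(pa, pb)$signal
  }, logical(1))
  expect_false(any(signals))
  expect_error(circular_permutation_score(
    domain_structure("s", test_trace(10, 1)), a),
    class = "rebelscan_too_short")
})

test_that("noise monotonicity: more noise raises mean RMSD and lowers TM on average", {
  stats_at <- function(sigma) {
    vals <- vapply(1:6, function(i) {
      sf <- make_superfamily(synthetic_spec(5, 60, sigma, seed = 130 + i))
      ens <- multiple_superpose(sf$alignment, sf$structures)
      m <- rmsd_matrix(sf$alignment, sf$structures, ens)
      tm <- tm_score(sf$alignment, sf$structures[[1]], sf$structures[[2]])
      c(mean_rmsd(m)[[1]], tm)
    }, numeric(2))
    rowMeans(vals)
  }
  lo <- stats_at(0.2); hi <- stats_at(1.0)
  expect_lt(lo[1], hi[1])
  expect_gt(lo[2], hi[2])
})

test_that("deviation_report recovers a planted two-hinge outlier with family label", {
  sf <- make_ensemble(83, n = 8, core = 120,
                      plan = list(list(member = 3,
                                       perturbations = plant_two_hinge_outlier(120))))
  dev <- deviation_report(sf$alignment, sf$structures, sf$ensemble,
                          tm_scope = "candidates")
  expect_identical(dev$outliers, "m03")
  expect_identical(dev$category, "single-outlier")
  expect_true(dev$family_specific)      # planted member is family "deviant"
  expect_identical(dev$family_label, "deviant")
  expect_gt(dev$mean_rmsd[["m03"]], 5.5)
  expect_lt(dev$tm_median[["m03"]], 0.5)
  ## one large outlier drags every member's mean RMSD up; the TM-score
  ## confirmation is what keeps the unperturbed members off the outlier list
  computed <- !is.na(dev$tm_median)
  expect_true(all(dev$tm_median[computed & names(dev$tm_median) != "m03"] > 0.5))
})
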