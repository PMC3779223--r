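## Deviation statistics: pairwise RMSD matrix in the common superposed
## frame, one-against-all MeanRMSD, TM-score confirmation, outlier calls,
## family-specificity, and heuristic screens for indels/terminal extensions
## and circular permutation.

#' Pairwise RMSD matrix over matched alignment columns
#'
#' Entry (a, b) is the RMSD over [pair_columns()] of the two members'
#' C-alpha coordinates.  By default the coordinates are taken in the common
#' frame produced by [multiple_superpose()] (the protocol order: superpose
#' the whole superfamily once, then read off pairwise deviations from the
#' matched C-alphas).  `mode = "repair"` instead re-superposes every pair
#' optimally with [kabsch()] before measuring; this always gives smaller or
#' equal values and is not the default.
#'
#' Pairs sharing fewer than 3 matched columns are set to `NA` with a warning
#' and excluded from means.
#'
#' @param aln A [multiple_alignment()].
#' @param structures List of [domain_structure()]s.
#' @param ensemble A `superposed_ensemble` from [multiple_superpose()]
#'   (required for `mode = "common-frame"`).
#' @param mode `"common-frame"` (default) or `"repair"`.
#' @return Symmetric numeric matrix (Angstrom) with zero diagonal and member
#'   ids as dimnames.
#' @export
rmsd_matrix <- function(aln, structures, ensemble = NULL,
                        mode = c("common-frame", "repair")) {
  mode <- match.arg(mode)
  names(structures) <- vapply(structures, function(s) s$member_id, character(1))
  ids <- aln$member_ids
  n <- length(ids)
  coords <- if (mode == "common-frame") {
    if (is.null(ensemble))
      abort("common-frame mode needs a superposed ensemble",
            "rebelscan_missing_ensemble")
    ensemble$superposed[ids]
  } else {
    lapply(structures[ids], function(s) s$xyz)
  }
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cols <- tryCatch(pair_columns(aln, ids[i], ids[j]),
                     rebelscan_too_few_matches = function(e) NULL)
    if (is.null(cols)) {
      warn(sprintf("pair %s/%s has < 3 matched columns; excluded from means",
                   ids[i], ids[j]), "rebelscan_pair_excluded")
      m[i, j] <- m[j, i] <- NA_real_
      next
    }
    xi <- coords[[ids[i]]][aln$rows[[ids[i]]][cols], , drop = FALSE]
    xj <- coords[[ids[j]]][aln$rows[[ids[j]]][cols], , drop = FALSE]
    r <- if (mode == "repair") kabsch(xi, xj)$rmsd
         else sqrt(sum((xi - xj)^2) / length(cols))
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' One-against-all mean RMSD
#'
#' The MeanRMSD statistic: for each member, the arithmetic mean of its
#' pairwise RMSDs against all other members.  A high value flags significant
#' structural variation of that member relative to the rest of the
#' superfamily.
#'
#' @param m Symmetric pairwise RMSD matrix (possibly with `NA` for excluded
#'   pairs).
#' @return Named numeric vector of per-member means (Angstrom).
#' @export
mean_rmsd <- function(m) {
  if (nrow(m) < 2L)
    abort("mean RMSD needs at least 2 members", "rebelscan_too_few_members")
  out <- vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, -i]
    if (all(is.na(v)))
      abort(sprintf("all pairs excluded for member %s", rownames(m)[i]),
            "rebelscan_all_pairs_missing")
    mean(v, na.rm = TRUE)
  }, numeric(1))
  stats::setNames(out, rownames(m))
}

#' TM-score parameters
#'
#' The TM-score distance scale is `d0 = 1.24 (L_N - 15)^(1/3) - 1.8`
#' Angstrom, floored at `d0_floor` (the cube-root formula goes negative for
#' normalisation lengths below about 21 residues).  `normalization` selects
#' `L_N`: the shorter member's residue count (default; conservative), the
#' longer one's, or the first/second argument's.
#'
#' @param normalization One of `"shorter"`, `"longer"`, `"first"`, `"second"`.
#' @param d0_floor Minimum d0 in Angstrom (> 0).
#' @return A list of class `tm_params`.
#' @export
tm_params <- function(normalization = c("shorter", "longer", "first", "second"),
                      d0_floor = 0.5) {
  normalization <- match.arg(normalization)
  stopifnot(d0_floor > 0)
  structure(list(normalization = normalization, d0_floor = d0_floor),
            class = "tm_params")
}

tm_d0 <- function(L_N, d0_floor) {
  v <- L_N - 15
  max(d0_floor, 1.24 * sign(v) * abs(v)^(1 / 3) - 1.8)
}

## Seed-and-extend TM-score maximisation over matched coordinate pairs.
## Every seed is a contiguous fragment superposed by Kabsch, then refined by
## iterating {keep pairs closer than d0 + 1 A (never fewer than 4),
## re-superpose} until the score is stable; the maximum score over all seeds
## and rounds is returned.  For short matched regions (L <= 60) every
## contiguous fragment of length >= 4 is tried, which makes the search
## exhaustive at negligible cost; longer regions use fragments of lengths
## ~{L, L/2, L/4} (minimum 4) at stride ~L/10.  Deterministic throughout.
tm_align <- function(X, Y, L_N, d0) {
  L <- nrow(X)
  exhaustive <- L <= 60L
  lens <- if (exhaustive) seq(L, 4L)
          else sort(unique(pmax(4L, floor(c(L, L / 2, L / 4)))),
                    decreasing = TRUE)
  stride <- if (exhaustive) 1L else max(1L, floor(L / 10))
  best <- 0
  score_of <- function(tr) {
    d2 <- rowSums((sweep(Y %*% t(tr$rotation), 2, tr$translation, "+") - X)^2)
    list(score = sum(1 / (1 + d2 / d0^2)) / L_N, d = sqrt(d2))
  }
  for (len in lens) {
    starts <- unique(c(seq(1L, L - len + 1L, by = stride), L - len + 1L))
    for (s in starts) {
      idx <- s:(s + len - 1L)
      tr <- kabsch(X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      sc <- score_of(tr)
      best <- max(best, sc$score)
      prev <- sc$score
      for (round in seq_len(20L)) {
        sel <- which(sc$d < d0 + 1)
        if (length(sel) < 4L) sel <- order(sc$d)[1:4]
        tr <- kabsch(X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
        sc <- score_of(tr)
        best <- max(best, sc$score)
        if (abs(sc$score - prev) < 1e-6) break
        prev <- sc$score
      }
    }
  }
  best
}

#' TM-score between two aligned members
#'
#' Length-normalised structural similarity in (0, 1]:
#' `TM = max over superpositions of (1/L_N) sum_i 1 / (1 + (d_i/d0)^2)`,
#' where the sum runs over the matched (pairwise ungapped) alignment columns,
#' `d_i` are post-superposition C-alpha distances and `d0` is the
#' length-dependent scale of [tm_params()].  Scores below about 0.5 indicate
#' structures of different folds.  Maximisation uses a deterministic
#' seed-and-extend search validated against an exhaustive-seed oracle on
#' small instances.
#'
#' @param aln A [multiple_alignment()].
#' @param a,b [domain_structure()] objects present in the alignment.
#' @param params A [tm_params()] object.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(aln, a, b, params = tm_params()) {
  cols <- pair_columns(aln, a$member_id, b$member_id)
  X <- member_coords_at(aln, a, cols)
  Y <- member_coords_at(aln, b, cols)
  L_N <- switch(params$normalization,
                shorter = min(nrow(a$xyz), nrow(b$xyz)),
                longer  = max(nrow(a$xyz), nrow(b$xyz)),
                first   = nrow(a$xyz),
                second  = nrow(b$xyz))
  tm_align(X, Y, L_N, tm_d0(L_N, params$d0_floor))
}

#' TM-score matrix (or candidate rows) for a superfamily
#'
#' @param aln A [multiple_alignment()].
#' @param structures List of [domain_structure()]s.
#' @param params A [tm_params()].
#' @param members Member ids for which rows are computed (default all).
#'   Because the outlier rule requires BOTH a high mean RMSD and a low
#'   TM-score, restricting rows to the high-RMSD candidates is sufficient
#'   for classification and much cheaper; unrequested entries are `NA`.
#' @return Symmetric matrix with `NA` diagonal and unvisited entries.
#' @export
tm_matrix <- function(aln, structures, params = tm_params(), members = NULL) {
  names(structures) <- vapply(structures, function(s) s$member_id, character(1))
  ids <- aln$member_ids
  members <- members %||% ids
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (a in members) for (b in ids) {
    if (a == b || !is.na(m[a, b])) next
    m[a, b] <- m[b, a] <- tm_score(aln, structures[[a]], structures[[b]],
                                   params)
  }
  m
}

#' Call structural outliers
#'
#' A member is a structural outlier when its one-against-all mean RMSD
#' strictly exceeds `rmsd_cut` (default 5.5 Angstrom) AND its TM-score
#' aggregate against the other members is strictly below `tm_cut` (default
#' 0.5); a member sitting exactly at a cut is not an outlier.  The TM
#' aggregate per member is the median of its pairwise TM-scores, robust to
#' one aberrant partner.  `rule = "or"` flags members passing either test.
#'
#' @param mean_rmsd Named vector from [mean_rmsd()].
#' @param tm_median Named vector of per-member median TM-scores (`NA`
#'   allowed for members whose mean RMSD already fails the cut under the
#'   `"and"` rule).
#' @param rmsd_cut Mean-RMSD threshold in Angstrom.
#' @param tm_cut TM-score threshold.
#' @param rule `"and"` (default) or `"or"`.
#' @return List: `outliers` (character vector), `category` (one of
#'   `"no-outlier"`, `"single-outlier"`, `"two-outlier"`,
#'   `"multiple-outlier"`), and the thresholds used.
#' @export
classify_outliers <- function(mean_rmsd, tm_median, rmsd_cut = 5.5,
                              tm_cut = 0.5, rule = c("and", "or")) {
  rule <- match.arg(rule)
  ids <- names(mean_rmsd)
  tm_median <- tm_median[ids]
  high_rmsd <- mean_rmsd > rmsd_cut
  low_tm <- !is.na(tm_median) & tm_median < tm_cut
  if (rule == "and") {
    if (any(high_rmsd & is.na(tm_median)))
      abort("TM aggregate missing for a high-RMSD candidate",
            "rebelscan_missing_tm")
    out <- ids[high_rmsd & low_tm]
  } else {
    if (anyNA(tm_median))
      abort("'or' rule needs TM aggregates for every member",
            "rebelscan_missing_tm")
    out <- ids[high_rmsd | low_tm]
  }
  category <- switch(as.character(min(length(out), 3L)),
                     "0" = "no-outlier", "1" = "single-outlier",
                     "2" = "two-outlier", "3" = "multiple-outlier")
  list(outliers = out, category = category,
       rmsd_cut = rmsd_cut, tm_cut = tm_cut, rule = rule)
}

#' Family specificity of an outlier set
#'
#' Outliers are family-specific when they all belong to one family and no
#' non-outlier shares that family -- the pattern in which a whole SCOP
#' family has diverged from the rest of its superfamily.
#'
#' @param outliers Character vector of outlier member ids (non-empty).
#' @param family_ids Named character vector mapping every member to its
#'   family.
#' @return List: `family_specific` (logical) and `label` (the family id when
#'   specific, otherwise `NA`).
#' @export
family_specificity <- function(outliers, family_ids) {
  if (length(outliers) == 0L)
    abort("family specificity is undefined without outliers",
          "rebelscan_no_outliers")
  fams <- unique(family_ids[outliers])
  rest <- family_ids[setdiff(names(family_ids), outliers)]
  ok <- length(fams) == 1L && !fams %in% rest
  list(family_specific = ok, label = if (ok) unname(fams) else NA_character_)
}

#' Full deviation report for a superfamily
#'
#' Runs the structural layer end-to-end: pairwise RMSD matrix in the common
#' superposed frame, MeanRMSD per member, TM-score confirmation, outlier
#' calls and family specificity.
#'
#' @inheritParams rmsd_matrix
#' @inheritParams classify_outliers
#' @param params A [tm_params()].
#' @param tm_scope `"all"` computes the full TM matrix (needed for complete
#'   reports and for `rule = "or"`); `"candidates"` computes TM only for
#'   members whose mean RMSD exceeds `rmsd_cut`, which is sufficient for
#'   classification under the `"and"` rule.
#' @return An object of class `deviation_report` with fields `member_ids`,
#'   `family_ids`, `rmsd_matrix`, `mean_rmsd`, `tm_matrix`, `tm_median`,
#'   `outliers`, `category`, `family_specific`, `family_label` and
#'   `thresholds`.
#' @export
deviation_report <- function(aln, structures, ensemble,
                             rmsd_cut = 5.5, tm_cut = 0.5,
                             params = tm_params(), rule = c("and", "or"),
                             mode = c("common-frame", "repair"),
                             tm_scope = c("all", "candidates")) {
  rule <- match.arg(rule); mode <- match.arg(mode)
  tm_scope <- match.arg(tm_scope)
  names(structures) <- vapply(structures, function(s) s$member_id, character(1))
  m <- rmsd_matrix(aln, structures, ensemble, mode = mode)
  mr <- mean_rmsd(m)
  cand <- if (tm_scope == "candidates" && rule == "and")
    names(mr)[mr > rmsd_cut] else aln$member_ids
  tmm <- tm_matrix(aln, structures, params, members = cand)
  tm_med <- apply(tmm, 1, function(v) stats::median(v, na.rm = TRUE))
  tm_med[is.nan(tm_med)] <- NA_real_
  ## symmetry fills stray entries in non-candidate rows; their aggregate is
  ## not meaningful under candidate scoping
  tm_med[setdiff(aln$member_ids, cand)] <- NA_real_
  cls <- classify_outliers(mr, tm_med, rmsd_cut, tm_cut, rule)
  fams <- stats::setNames(
    vapply(structures[aln$member_ids], function(s) s$family_id, character(1)),
    aln$member_ids)
  fs <- if (length(cls$outliers) > 0L) family_specificity(cls$outliers, fams)
        else list(family_specific = FALSE, label = NA_character_)
  structure(list(member_ids = aln$member_ids, family_ids = fams,
                 rmsd_matrix = m, mean_rmsd = mr, tm_matrix = tmm,
                 tm_median = tm_med, outliers = cls$outliers,
                 category = cls$category,
                 family_specific = fs$family_specific,
                 family_label = fs$label,
                 thresholds = list(rmsd_cut = rmsd_cut, tm_cut = tm_cut,
                                   rule = rule, mode = mode)),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat(sprintf("<deviation_report> %d members; category %s; outliers: %s%s\n",
              length(x$member_ids), x$category,
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none",
              if (x$family_specific)
                sprintf(" (family-specific: %s)", x$family_label) else ""))
  invisible(x)
}

#' Gap-run summary for one member
#'
#' Heuristic screen for the alignment signatures of indels and terminal
#' extensions.  An insertion run is a maximal stretch of columns where the
#' member has residues but more than half of the other members are gapped; a
#' deletion run is the converse.  Insertion runs touching the alignment ends
#' are relabelled N-/C-terminal extensions (extra structure beyond the
#' common core); deletion runs keep their label at the termini.
#'
#' @param aln A [multiple_alignment()].
#' @param member Member id.
#' @return Data frame with columns `kind` (one of `"insertion"`,
#'   `"deletion"`, `"N-terminal-extension"`, `"C-terminal-extension"`),
#'   `start_col`, `length`; zero rows for an unremarkable member.
#' @export
gap_run_summary <- function(aln, member) {
  if (!member %in% aln$member_ids)
    abort(sprintf("unknown member: %s", member), "rebelscan_unknown_member")
  others <- setdiff(aln$member_ids, member)
  self_gap <- is.na(aln$rows[[member]])
  other_gap_frac <- Reduce(`+`, lapply(aln$rows[others], is.na)) /
    length(others)
  state <- ifelse(!self_gap & other_gap_frac > 0.5, "insertion",
                  ifelse(self_gap & (1 - other_gap_frac) > 0.5, "deletion",
                         "none"))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  kind <- r$values[keep]; start_col <- starts[keep]; len <- r$lengths[keep]
  if (length(kind)) {
    touch_start <- start_col == 1L
    touch_end <- start_col + len - 1L == aln$n_col
    kind[kind == "insertion" & touch_start] <- "N-terminal-extension"
    kind[kind == "insertion" & touch_end] <- "C-terminal-extension"
  }
  data.frame(kind = kind, start_col = start_col, length = len,
             stringsAsFactors = FALSE)
}

#' Circular-permutation screening score for a member pair
#'
#' Screens whether cyclically re-ordering member `b`'s residues brings it
#' much closer to member `a`: for each cyclic shift k (coarse grid of
#' `grid_step` residues, then +/- `refine` around the best), correspondences
#' are re-derived positionally over the min-length overlap, the pair is
#' superposed by [kabsch()] and the RMSD recorded.  A large improvement of
#' the best shift over shift 0 is the signature of a circular permutation;
#' this is a screening hint, not a full CP detector.
#'
#' @param a,b [domain_structure()]s with at least 20 residues each.
#' @param grid_step Coarse grid spacing in residues.
#' @param refine Half-width of local refinement around the best grid shift.
#' @param cp_tol Minimum improvement (Angstrom) to report a CP signal.
#' @return List: `best_shift`, `improvement` (Angstrom), `rmsd_unshifted`,
#'   `rmsd_best`, `signal` (logical; `FALSE` means "no CP signal").
#' @export
circular_permutation_score <- function(a, b, grid_step = 5L, refine = 4L,
                                       cp_tol = 2.0) {
  na <- nrow(a$xyz); nb <- nrow(b$xyz)
  if (na < 20L || nb < 20L)
    abort("circular-permutation screen needs >= 20 residues per member",
          "rebelscan_too_short")
  n <- min(na, nb)
  X <- a$xyz[seq_len(n), , drop = FALSE]
  ## undo a cyclic shift of k on b: residue i of a is compared with residue
  ## i - k of b, so the reported best shift equals the shift b carries
  rmsd_at <- function(k) {
    idx <- ((seq_len(n) - 1L - k) %% nb) + 1L
    kabsch(X, b$xyz[idx, , drop = FALSE])$rmsd
  }
  shifts <- unique(c(0L, seq(0L, nb - 1L, by = grid_step)))
  r <- vapply(shifts, rmsd_at, numeric(1))
  best <- shifts[which.min(r)]
  fine <- unique(pmax(0L, pmin(nb - 1L, best + (-refine):refine)))
  rf <- vapply(fine, rmsd_at, numeric(1))
  best <- fine[which.min(rf)]
  rmsd0 <- rmsd_at(0L)
  rmsd_best <- min(rf)
  imp <- rmsd0 - rmsd_best
  list(best_shift = best, improvement = imp, rmsd_unshifted = rmsd0,
       rmsd_best = rmsd_best, signal = imp > cp_tol)
}
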