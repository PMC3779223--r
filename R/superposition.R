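## Rigid-body superposition: pairwise Kabsch and iterative consensus
## (multiple) superposition over alignment-derived equivalences.

#' Optimal rigid superposition of two matched point sets (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising
#' `sum_i || R y_i + t - x_i ||^2` over all rigid motions, by SVD of the
#' cross-covariance matrix with sign correction of the smallest singular
#' direction so that reflections are never returned (mirror-image
#' superposition is physically meaningless for protein backbones).
#'
#' @param X Target n x 3 coordinate matrix (Angstrom).
#' @param Y Moving n x 3 coordinate matrix, matched row-by-row with `X`.
#' @return A list of class `rigid_transform` with elements `rotation`
#'   (3 x 3, det +1), `translation` (length 3) and `rmsd` (Angstrom),
#'   plus `degenerate = TRUE` when the point sets have rank < 2 (collinear),
#'   in which case the minimiser is not unique.
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L || nrow(Y) != n || ncol(X) != 3L || ncol(Y) != 3L)
    abort("kabsch needs two matched n x 3 sets with n >= 3",
          "rebelscan_bad_points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  H <- crossprod(Yc, Xc)                # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  degenerate <- sum(sv$d > max(sv$d) * 1e-9) < 2L
  t_vec <- as.numeric(cx - R %*% cy)
  dev <- Xc - Yc %*% t(R)
  rmsd <- sqrt(sum(dev^2) / n)
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 degenerate = degenerate),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param tr A `rigid_transform`.
#' @param xyz n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(tr, xyz) {
  sweep(as.matrix(xyz) %*% t(tr$rotation), 2, tr$translation, "+")
}

#' Fully-ungapped (core) alignment columns
#'
#' The equivalences used for multiple superposition: columns with no gap in
#' any member, in alignment order.
#'
#' @param aln A [multiple_alignment()].
#' @return Integer vector of 1-based column indices.
#' @export
core_columns <- function(aln) {
  gap <- Reduce(`|`, lapply(aln$rows, is.na))
  cols <- which(!gap)
  if (length(cols) == 0L)
    abort("alignment has no fully-ungapped column: superfamily members share no common core",
          "rebelscan_no_core")
  cols
}

#' Columns ungapped in both members of a pair
#'
#' The matched positions from which a pairwise RMSD is computed; a superset
#' of [core_columns()].
#'
#' @param aln A [multiple_alignment()].
#' @param a,b Member ids.
#' @return Integer vector of 1-based column indices.
#' @export
pair_columns <- function(aln, a, b) {
  if (!a %in% aln$member_ids || !b %in% aln$member_ids)
    abort(sprintf("unknown member(s): %s",
                  paste(setdiff(c(a, b), aln$member_ids), collapse = ", ")),
          "rebelscan_unknown_member")
  cols <- which(!is.na(aln$rows[[a]]) & !is.na(aln$rows[[b]]))
  if (length(cols) < 3L)
    abort(sprintf("members %s and %s share fewer than 3 aligned positions",
                  a, b), "rebelscan_too_few_matches")
  cols
}

## Coordinates of a member at given alignment columns (rows with residues).
member_coords_at <- function(aln, s, cols) {
  s$xyz[aln$rows[[s$member_id]][cols], , drop = FALSE]
}

#' Iterative multiple superposition onto a consensus
#'
#' Superposes all members into one common frame over the core equivalences:
#' the consensus is initialised from the reference member (the member with
#' the most aligned positions; ties broken by lexicographic id), then the
#' procedure alternates between superposing every member onto the consensus
#' by [kabsch()] over the core columns and recomputing the consensus as the
#' coordinate-wise mean of the superposed members, until the largest
#' consensus-point displacement between iterations drops below `tol` or
#' `max_iter` is reached.  Input structures are never modified.
#'
#' @param aln A [multiple_alignment()].
#' @param structures List of [domain_structure()] objects covering the
#'   alignment's members.
#' @param tol Convergence tolerance on maximum consensus displacement
#'   (Angstrom).
#' @param max_iter Iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @param reference Optional member id overriding the default reference rule.
#' @return A list of class `superposed_ensemble`: `member_ids`, `transforms`
#'   (per member a `rigid_transform`), `superposed` (per member the full
#'   transformed coordinate matrix), `consensus` (core-length n x 3 matrix),
#'   `core_cols`, `iterations_run`, `converged`, and `rmsd_to_consensus`.
#' @export
multiple_superpose <- function(aln, structures, tol = 0.01, max_iter = 100L,
                               reference = NULL) {
  names(structures) <- vapply(structures, function(s) s$member_id, character(1))
  if (length(structures) < 2L)
    abort("multiple superposition needs at least 2 members",
          "rebelscan_too_few_members")
  mism <- validate_alignment(aln, structures)
  if (nrow(mism) > 0L)
    abort(sprintf("alignment/structure residue-count mismatch for: %s",
                  paste(mism$member_id, collapse = ", ")),
          "rebelscan_invalid_alignment")
  cols <- core_columns(aln)
  if (length(cols) < 3L)
    abort("fewer than 3 core columns", "rebelscan_too_few_matches")

  if (is.null(reference)) {
    aligned <- vapply(aln$rows, function(r) sum(!is.na(r)), integer(1))
    ord <- order(-aligned, aln$member_ids)
    reference <- aln$member_ids[ord[1]]
  }
  ids <- aln$member_ids
  core <- lapply(ids, function(m) member_coords_at(aln, structures[[m]], cols))
  names(core) <- ids

  consensus <- core[[reference]]
  iterations <- 0L
  converged <- FALSE
  transforms <- NULL
  while (iterations < max_iter) {
    iterations <- iterations + 1L
    transforms <- lapply(ids, function(m) kabsch(consensus, core[[m]]))
    names(transforms) <- ids
    fitted <- lapply(ids, function(m) apply_transform(transforms[[m]],
                                                      core[[m]]))
    new_cons <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(max(rowSums((new_cons - consensus)^2)))
    consensus <- new_cons
    if (shift < tol) { converged <- TRUE; break }
  }
  ## final fit of every member onto the converged consensus
  transforms <- lapply(ids, function(m) kabsch(consensus, core[[m]]))
  names(transforms) <- ids
  superposed <- lapply(ids, function(m)
    apply_transform(transforms[[m]], structures[[m]]$xyz))
  names(superposed) <- ids
  rmsd_cons <- vapply(ids, function(m) transforms[[m]]$rmsd, numeric(1))
  structure(list(member_ids = ids, transforms = transforms,
                 superposed = superposed, consensus = consensus,
                 core_cols = cols, reference = reference,
                 iterations_run = iterations, converged = converged,
                 rmsd_to_consensus = rmsd_cons),
            class = "superposed_ensemble")
}

#' @export
print.superposed_ensemble <- function(x, ...) {
  cat(sprintf("<superposed_ensemble> %d members on %d core columns; %d iterations (%s); reference %s\n",
              length(x$member_ids), length(x$core_cols), x$iterations_run,
              if (x$converged) "converged" else "NOT converged", x$reference))
  invisible(x)
}
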