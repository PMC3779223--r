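## Synthetic superfamilies with planted perturbations, plus toy GO
## ontologies with planted annotation structure.  Every generated object
## carries a ground-truth record so recovery experiments can score
## themselves.  All randomness flows through one seeded RNG per call, in a
## fixed draw order, so outputs are byte-reproducible per seed.

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

unit <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

## Rodrigues rotation matrix for angle (degrees) about a unit axis.
rotation_about <- function(axis, angle_deg) {
  a <- unit(axis); th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

random_rotation <- function() {
  ## QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a protein-like C-alpha core trace
#'
#' Builds a smooth self-avoiding 3D trace with consecutive C-alpha spacing
#' 3.8 Angstrom, alternating idealised helical turns (radius 2.3 A, rise
#' 1.5 A/residue, 100 degrees/residue) with short extended segments, the
#' chain axis re-orienting slightly between segments.  Deterministic per
#' seed; candidate traces with non-consecutive contacts closer than 2.2 A
#' are rejected and redrawn from the same stream.
#'
#' @param length Number of residues (>= 30).
#' @param seed Integer seed.
#' @return A `length` x 3 coordinate matrix in Angstrom.
#' @export
generate_core_backbone <- function(length, seed) {
  if (length < 30L)
    abort("core length must be at least 30 residues", "rebelscan_bad_spec")
  with_seed(seed, {
    best <- NULL; best_min <- -Inf
    for (attempt in seq_len(50L)) {
      x <- one_trace_attempt(length)
      d <- as.matrix(stats::dist(x))
      d[abs(row(d) - col(d)) <= 1L] <- Inf
      md <- min(d)
      if (md > best_min) { best <- x; best_min <- md }
      if (md > 2.2) break
    }
    best
  })
}

one_trace_attempt <- function(length) {
  axis <- unit(stats::rnorm(3))
  u <- unit(cross3(axis, if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  v <- cross3(axis, u)
  pts <- matrix(0, length, 3)
  i <- 1L
  theta <- stats::runif(1, 0, 2 * pi)
  helix <- TRUE
  while (i < length) {
    seg_len <- if (helix) sample(9:13, 1) else sample(4:6, 1)
    for (k in seq_len(min(seg_len, length - i))) {
      if (helix) {
        dtheta <- 100 * pi / 180
        step <- 1.5 * axis +
          2.3 * ((cos(theta + dtheta) - cos(theta)) * u +
                 (sin(theta + dtheta) - sin(theta)) * v)
        theta <- theta + dtheta
      } else {
        step <- axis + 0.15 * (if (i %% 2L == 0L) u else -u)
      }
      pts[i + 1L, ] <- pts[i, ] + 3.8 * unit(step)
      i <- i + 1L
    }
    ## re-orient the segment axis by a small random turn
    turn <- rotation_about(unit(cos(stats::runif(1, 0, 2 * pi)) * u +
                                sin(stats::runif(1, 0, 2 * pi)) * v),
                           stats::runif(1, 8, 20))
    axis <- unit(as.numeric(turn %*% axis))
    u <- unit(cross3(axis, if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    v <- cross3(axis, u)
    helix <- !helix
  }
  pts
}

#' Perturbation descriptors
#'
#' Constructors for the planted structural perturbations a synthetic member
#' can carry: `hinge` rigid-body rotation of a residue range about an axis
#' through the range's first C-alpha, `insertion`/`deletion` of residues,
#' `circular_permutation` of the chain order, and `segment_swap` of two
#' equal-length ranges.  `axis_choice` selects one of two deterministic,
#' mutually orthogonal axes perpendicular to the local chain direction at
#' the hinge point.
#'
#' @param range Integer `c(start, end)` residue range (1-based, inclusive).
#' @param angle_deg Rotation angle in (0, 180].
#' @param axis_choice 1 or 2.
#' @return A list of class `perturbation`.
#' @export
hinge <- function(range, angle_deg, axis_choice = 1L) {
  stopifnot(length(range) == 2L, range[1] <= range[2],
            angle_deg > 0, angle_deg <= 180)
  structure(list(kind = "hinge", range = as.integer(range),
                 angle_deg = angle_deg, axis_choice = as.integer(axis_choice)),
            class = "perturbation")
}

#' @rdname hinge
#' @param position Residue position (insertion: inserted after it;
#'   deletion: first deleted residue).
#' @param length Number of residues inserted or deleted.
#' @export
insertion <- function(position, length) {
  structure(list(kind = "insertion", position = as.integer(position),
                 length = as.integer(length)), class = "perturbation")
}

#' @rdname hinge
#' @export
deletion <- function(position, length) {
  structure(list(kind = "deletion", position = as.integer(position),
                 length = as.integer(length)), class = "perturbation")
}

#' @rdname hinge
#' @param shift Cyclic shift in residues: the new chain starts at residue
#'   `shift + 1` of the old order.
#' @export
circular_permutation <- function(shift) {
  structure(list(kind = "circular_permutation", shift = as.integer(shift)),
            class = "perturbation")
}

#' @rdname hinge
#' @param range2 Second range, same length as `range`.
#' @export
segment_swap <- function(range, range2) {
  stopifnot(diff(range) == diff(range2))
  structure(list(kind = "segment_swap", range = as.integer(range),
                 range2 = as.integer(range2)), class = "perturbation")
}

#' Canonical two-hinge outlier plan
#'
#' The package's reference "structurally deviant member": the final two
#' thirds of the chain are rotated away block-wise -- residues
#' `[L/3+1, 2L/3]` by 120 degrees and `[2L/3+1, L]` by 150 degrees about
#' orthogonal axes through the respective hinge points -- leaving a largest
#' rigid block of `L/3` residues, so no single superposition can align much
#' more than a third of the member well.
#'
#' @param core_length Core length `L` (>= 90).
#' @return List of two [hinge()] perturbations.
#' @export
plant_two_hinge_outlier <- function(core_length = 120L) {
  if (core_length < 90L)
    abort("two-hinge plan needs a core of at least 90 residues",
          "rebelscan_bad_spec")
  L <- as.integer(core_length)
  b <- L %/% 3L
  list(hinge(c(b + 1L, 2L * b), 120, axis_choice = 1L),
       hinge(c(2L * b + 1L, L), 150, axis_choice = 2L))
}

#' Synthetic superfamily specification
#'
#' @param n_members Number of members (>= 2).
#' @param core_length Conserved-core length in residues (>= 30).
#' @param noise_sd Isotropic per-atom Gaussian coordinate noise (Angstrom).
#' @param outlier_plan Named-by-nothing list of entries
#'   `list(member = <index>, perturbations = <list of [hinge()] etc.>)`.
#' @param seed Integer seed governing every random draw.
#' @param family_plan Optional named character vector member id -> family
#'   id; by default perturbed members form family `"deviant"` and the rest
#'   family `"core"`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_members, core_length = 120L, noise_sd = 0.3,
                           outlier_plan = list(), seed = 1L,
                           family_plan = NULL) {
  stopifnot(n_members >= 2L, core_length >= 30L, noise_sd >= 0)
  idx <- vapply(outlier_plan, function(p) p$member, numeric(1))
  if (length(idx) && (any(idx < 1L | idx > n_members) || anyDuplicated(idx)))
    abort("outlier_plan member indices invalid", "rebelscan_bad_spec")
  structure(list(n_members = as.integer(n_members),
                 core_length = as.integer(core_length),
                 noise_sd = noise_sd, outlier_plan = outlier_plan,
                 seed = as.integer(seed), family_plan = family_plan),
            class = "synthetic_spec")
}

member_id_of <- function(i) sprintf("m%02d", i)

## Deterministic orthogonal hinge axes from the local chain geometry.
hinge_axes <- function(xyz, h) {
  n <- nrow(xyz)
  tangent <- unit(xyz[min(h + 1L, n), ] - xyz[max(h - 1L, 1L), ])
  ref <- if (abs(tangent[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a1 <- unit(cross3(tangent, ref))
  a2 <- unit(cross3(tangent, a1))
  list(a1, a2)
}

apply_perturbation <- function(xyz, p) {
  n <- nrow(xyz)
  switch(p$kind,
    hinge = {
      h <- p$range[1]
      ax <- hinge_axes(xyz, h)[[p$axis_choice]]
      R <- rotation_about(ax, p$angle_deg)
      idx <- p$range[1]:min(p$range[2], n)
      origin <- xyz[h, ]
      xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, origin) %*% t(R),
                          2, origin, "+")
      xyz
    },
    circular_permutation = {
      s <- p$shift %% n
      xyz[c((s + 1L):n, seq_len(s)), , drop = FALSE]
    },
    segment_swap = {
      i1 <- p$range[1]:p$range[2]; i2 <- p$range2[1]:p$range2[2]
      tmp <- xyz[i1, , drop = FALSE]
      xyz[i1, ] <- xyz[i2, , drop = FALSE]
      xyz[i2, ] <- tmp
      xyz
    },
    xyz)
}

## Short protruding excursion for inserted residues, 3.8 A spacing,
## pointing away from the chain at the insertion point.
insertion_coords <- function(xyz, after, len) {
  n <- nrow(xyz)
  base <- xyz[max(after, 1L), ]
  nxt <- xyz[min(after + 1L, n), ]
  tangent <- unit(if (all(nxt == base)) c(1, 0, 0) else nxt - base)
  away <- unit(base - colMeans(xyz))
  dirv <- unit(away - sum(away * tangent) * tangent +
               0.2 * stats::rnorm(3))
  half <- ceiling(len / 2)
  out <- matrix(NA_real_, len, 3)
  for (k in seq_len(len)) {
    arm <- if (k <= half) k else (len - k + 1L)
    lateral <- 0.8 * (k - len / 2)
    out[k, ] <- base + 3.8 * arm * dirv + lateral * tangent
  }
  out
}

#' Generate a synthetic superfamily
#'
#' Emulates the statistical structure of a multi-member superfamily: every
#' member is the same conserved core plus isotropic Gaussian coordinate
#' noise, placed in its own random rigid frame; members listed in the
#' outlier plan additionally carry their planted perturbations.  The
#' returned alignment is the structure-alignment truth: core columns map
#' surviving core residues across members, insertion columns are gapped in
#' all non-carriers, deletions are gapped in the carrier.  Circularly
#' permuted (and segment-swapped) members are emitted with the PERMUTED
#' residue order under a positionally naive alignment row -- as a real
#' alignment pipeline would produce for such a pair -- so they surface as
#' high-RMSD members.
#'
#' Draw order per seed: core trace, column letters, then per member (in
#' index order) its insertion geometry, noise and rigid frame.
#'
#' @param spec A [synthetic_spec()].
#' @return List: `structures` (list of [domain_structure()]),
#'   `alignment` (a [multiple_alignment()]), `families` (named character
#'   vector), `truth` (list of class `synthetic_truth`: `planted_outliers`,
#'   `perturbations`, `insertion_columns`, `spec`).
#' @export
make_superfamily <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- spec$core_length
  plan <- stats::setNames(
    lapply(spec$outlier_plan, `[[`, "perturbations"),
    member_id_of(vapply(spec$outlier_plan, function(p) p$member, numeric(1))))
  ids <- member_id_of(seq_len(spec$n_members))

  core <- generate_core_backbone(L, spec$seed)
  with_seed(spec$seed + 1e6L, {
    col_letter <- sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                         L, replace = TRUE)

    ## column skeleton: core positions, with insertion columns spliced in
    col_core <- seq_len(L)                 # core position of each column
    col_owner <- rep(NA_character_, L)     # carrier of an insertion column
    structures <- list()
    pert_rec <- list()

    for (i in seq_len(spec$n_members)) {
      id <- ids[i]
      perts <- plan[[id]] %||% list()
      kinds <- vapply(perts, `[[`, character(1), "kind")
      if (any(kinds %in% c("circular_permutation", "segment_swap")) &&
          any(kinds %in% c("insertion", "deletion")))
        abort("cannot combine reordering and indel perturbations in one member",
              "rebelscan_bad_spec")
      xyz <- core
      deleted <- integer()
      inserts <- list()
      for (p in perts) {
        if (p$kind == "insertion") inserts <- c(inserts, list(p))
        else if (p$kind == "deletion")
          deleted <- c(deleted, p$position:(p$position + p$length - 1L))
        else xyz <- apply_perturbation(xyz, p)
      }
      if (length(deleted) >= L)
        abort("deletions would empty the core", "rebelscan_bad_spec")
      keep <- setdiff(seq_len(L), deleted)
      xyz <- xyz[keep, , drop = FALSE]

      ## splice this member's insertion columns into the global skeleton;
      ## prev_ins tracks residues this member already gained, so a second
      ## insertion downstream of the first lands at the right row
      prev_ins <- data.frame(core_pos = integer(), len = integer())
      for (p in inserts) {
        at <- max(which(!is.na(col_core) & col_core <= p$position), 0L)
        col_core <- append(col_core, rep(NA_integer_, p$length), after = at)
        col_owner <- append(col_owner, rep(id, p$length), after = at)
        pos_in_member <- sum(keep <= p$position) +
          sum(prev_ins$len[prev_ins$core_pos <= p$position])
        ins_xyz <- insertion_coords(xyz, pos_in_member, p$length)
        xyz <- rbind(xyz[seq_len(pos_in_member), , drop = FALSE], ins_xyz,
                     xyz[-seq_len(pos_in_member), , drop = FALSE])
        prev_ins <- rbind(prev_ins, data.frame(core_pos = p$position,
                                               len = p$length))
      }

      if (spec$noise_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * nrow(xyz), sd = spec$noise_sd),
                            ncol = 3)
      R <- random_rotation()
      xyz <- xyz %*% t(R) + matrix(stats::runif(3, -30, 30),
                                   nrow(xyz), 3, byrow = TRUE)
      structures[[id]] <- list(xyz = xyz, deleted = deleted)
      pert_rec[[id]] <- perts
    }

    ## assemble gapped rows over the final column skeleton
    n_col <- length(col_core)
    seqs <- vapply(ids, function(id) {
      del <- structures[[id]]$deleted
      ch <- character(n_col)
      for (j in seq_len(n_col)) {
        cp <- col_core[j]
        ch[j] <- if (!is.na(cp)) {
          if (cp %in% del) "-" else col_letter[cp]
        } else if (identical(col_owner[j], id)) "A" else "-"
      }
      paste(ch, collapse = "")
    }, character(1))

    families <- spec$family_plan %||% stats::setNames(
      ifelse(ids %in% names(plan), "deviant", "core"), ids)
    doms <- lapply(ids, function(id)
      domain_structure(id, structures[[id]]$xyz, family_id = families[[id]]))
    names(doms) <- ids
    ins_cols <- lapply(stats::setNames(nm = names(plan)),
                       function(id) which(col_owner == id))
    ins_cols <- ins_cols[lengths(ins_cols) > 0L]
    truth <- structure(list(planted_outliers = names(plan),
                            perturbations = pert_rec,
                            insertion_columns = ins_cols,
                            spec = spec),
                       class = "synthetic_truth")
    list(structures = doms, alignment = multiple_alignment(seqs),
         families = families, truth = truth)
  })
}

#' Generate a toy GO ontology with planted branch structure
#'
#' A single root with `n_branches` disjoint `is_a` chains of the given
#' depth; terms at depth 3 or more occasionally (probability `p_shortcut`)
#' carry an additional `part_of` shortcut to their great-grandparent,
#' creating diamond motifs that exercise the part_of propagation weight.
#' Branch 1 is reserved for planted-outlier families by
#' [plant_annotations()], so that outliers' annotations share no ancestry
#' with the rest below the root.
#'
#' @param n_branches Number of branches (>= 2).
#' @param depth Chain depth (>= 2).
#' @param seed Integer seed.
#' @param p_shortcut Probability of a part_of shortcut per eligible term.
#' @return List: `onto` (a [go_ontology()]), `branch_terms` (list of term
#'   id vectors per branch, shallow to deep), `root`.
#' @export
generate_toy_ontology <- function(n_branches, depth, seed, p_shortcut = 0.3) {
  stopifnot(n_branches >= 2L, depth >= 2L)
  with_seed(seed, {
    root <- "GO:0000001"
    term_id <- function(b, d) sprintf("GO:%07d", 1L + b * 1000L + d)
    ids <- root; nms <- "toy root"
    ch <- character(); pa <- character(); ty <- character()
    branch_terms <- vector("list", n_branches)
    for (b in seq_len(n_branches)) {
      for (d in seq_len(depth)) {
        t <- term_id(b, d)
        ids <- c(ids, t); nms <- c(nms, sprintf("branch %d depth %d", b, d))
        parent <- if (d == 1L) root else term_id(b, d - 1L)
        ch <- c(ch, t); pa <- c(pa, parent); ty <- c(ty, "is_a")
        if (d >= 3L && stats::runif(1) < p_shortcut) {
          ggp <- if (d == 3L) root else term_id(b, d - 3L)
          ch <- c(ch, t); pa <- c(pa, ggp); ty <- c(ty, "part_of")
        }
        branch_terms[[b]] <- c(branch_terms[[b]], t)
      }
    }
    onto <- go_ontology(ids, nms, data.frame(child = ch, parent = pa,
                                             type = ty,
                                             stringsAsFactors = FALSE))
    list(onto = onto, branch_terms = branch_terms, root = root)
  })
}

#' Plant branch-disjoint annotations
#'
#' Assigns GO terms to members so that planted-outlier families draw only
#' from the reserved branch 1 while all other members draw from the
#' remaining branches of the toy ontology -- the annotation contrast under
#' which structural outliers also become functional outliers.
#'
#' @param members Character vector of member ids.
#' @param planted_outliers Subset of `members` forming the outlier families.
#' @param onto_plan Result of [generate_toy_ontology()].
#' @param terms_per_member Annotations per member.
#' @param seed Integer seed.
#' @return Named list member id -> character vector of GO ids.
#' @export
plant_annotations <- function(members, planted_outliers, onto_plan,
                              terms_per_member = 2L, seed = 1L) {
  nb <- length(onto_plan$branch_terms)
  stopifnot(nb >= 2L)
  with_seed(seed, {
    out <- lapply(members, function(m) {
      pool <- if (m %in% planted_outliers) onto_plan$branch_terms[[1]]
              else unlist(onto_plan$branch_terms[-1])
      sample(pool, min(terms_per_member, length(pool)))
    })
    stats::setNames(out, members)
  })
}
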