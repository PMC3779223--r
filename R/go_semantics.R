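## Wang-method GO semantic similarity over an OBO-parsed DAG, with the
## two-level aggregation used for superfamilies: all-term-pairs mean per
## domain pair, grand average per member, and outlier-vs-non-outlier
## group means.

#' Wang semantic contribution factors
#'
#' Per-edge-type factors by which a term's semantic value decays when
#' propagated to a parent: 0.8 for `is_a` and 0.6 for `part_of` edges, the
#' conventional choices of the Wang method.
#'
#' @param w_is_a,w_part_of Factors in (0, 1).
#' @return A list of class `wang_weights`.
#' @export
wang_weights <- function(w_is_a = 0.8, w_part_of = 0.6) {
  stopifnot(w_is_a > 0, w_is_a < 1, w_part_of > 0, w_part_of < 1)
  structure(list(is_a = w_is_a, part_of = w_part_of),
            class = "wang_weights")
}

#' Construct a GO ontology DAG
#'
#' @param terms Character vector of term ids.
#' @param names Character vector of term names (same length).
#' @param edges Data frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`); may have zero rows.
#' @return A list of class `go_ontology` with `terms`, `term_names`,
#'   `edges`, `roots` and a child-indexed adjacency list `parents_of`.
#' @export
go_ontology <- function(terms, names = terms, edges) {
  terms <- as.character(terms)
  if (anyDuplicated(terms))
    abort("duplicate term ids", "rebelscan_bad_ontology")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    if (!all(edges$type %in% c("is_a", "part_of")))
      abort("edge types limited to is_a and part_of", "rebelscan_bad_ontology")
    undef <- setdiff(unique(c(edges$child, edges$parent)), terms)
    if (length(undef))
      abort(sprintf("edges reference undefined terms: %s",
                    paste(undef, collapse = ", ")),
            "rebelscan_undefined_term")
  }
  ## Kahn's algorithm: every term must be removable, else the graph cycles
  indeg <- table(factor(edges$parent, levels = terms))
  remaining <- stats::setNames(as.integer(indeg), terms)
  queue <- terms[remaining == 0L]
  seen <- 0L
  parents_by_child <- split(seq_len(nrow(edges)), edges$child)
  child_edges <- split(seq_len(nrow(edges)), edges$child)
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (e in child_edges[[t]] %||% integer()) {
      p <- edges$parent[e]
      remaining[p] <- remaining[p] - 1L
      if (remaining[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(terms))
    abort("ontology graph contains a cycle", "rebelscan_cyclic_ontology")
  roots <- setdiff(terms, edges$child)
  structure(list(terms = terms,
                 term_names = stats::setNames(as.character(names), terms),
                 edges = edges, roots = roots,
                 parents_of = parents_by_child),
            class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("<go_ontology> %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (fields `id`, `name`, `is_a`,
#' `relationship: part_of`, `is_obsolete`).  Obsolete terms are skipped;
#' relationship types other than `part_of` are ignored with a warning.
#'
#' @param path Path to an OBO file.
#' @return A [go_ontology()].
#' @export
parse_obo <- function(path) {
  if (!file.exists(path))
    abort(sprintf("OBO file not found: %s", path), "rebelscan_missing_file")
  lines <- readLines(path, warn = FALSE)
  stanza_at <- which(lines == "[Term]")
  ids <- character(); nms <- character()
  ch <- character(); pa <- character(); ty <- character()
  bounds <- c(stanza_at, length(lines) + 1L)
  for (k in seq_along(stanza_at)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[!grepl("^\\[", block)]
    get <- function(key) sub(paste0("^", key, ":\\s*"), "",
                             grep(paste0("^", key, ":"), block, value = TRUE))
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- get("id")[1]
    if (is.na(id)) next
    ids <- c(ids, id)
    nms <- c(nms, get("name")[1] %||% id)
    for (p in get("is_a")) {
      ch <- c(ch, id); pa <- c(pa, sub("\\s*!.*$", "", p)); ty <- c(ty, "is_a")
    }
    for (rel in get("relationship")) {
      parts <- strsplit(trimws(sub("\\s*!.*$", "", rel)), "\\s+")[[1]]
      if (parts[1] == "part_of") {
        ch <- c(ch, id); pa <- c(pa, parts[2]); ty <- c(ty, "part_of")
      } else {
        warn(sprintf("ignoring relationship type '%s' on %s", parts[1], id),
             "rebelscan_unknown_relationship")
      }
    }
  }
  ## drop edges pointing at obsolete (skipped) parents silently is unsafe;
  ## go_ontology() errors on undefined parents instead
  go_ontology(ids, nms, data.frame(child = ch, parent = pa, type = ty,
                                   stringsAsFactors = FALSE))
}

#' Write a toy ontology as OBO 1.2
#' @param onto A [go_ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (t in onto$terms) {
    e <- onto$edges[onto$edges$child == t, , drop = FALSE]
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", onto$term_names[[t]]),
             if (nrow(e)) unlist(lapply(seq_len(nrow(e)), function(i)
               if (e$type[i] == "is_a") paste0("is_a: ", e$parent[i])
               else paste0("relationship: part_of ", e$parent[i]))),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Wang S-values of a term
#'
#' Semantic contributions of a term's ancestors to its meaning:
#' `S(t) = 1` for the term itself, and for each ancestor `u`,
#' `S(u) = max over child edges c -> u on paths from t of w(c -> u) * S(c)`,
#' computed by upward dynamic programming over the DAG.
#'
#' @param term A term id present in the ontology.
#' @param onto A [go_ontology()].
#' @param w A [wang_weights()].
#' @return Named numeric vector over the term and all its ancestors.
#' @export
svalues <- function(term, onto, w = wang_weights()) {
  if (!term %in% onto$terms)
    abort(sprintf("unknown term: %s", term), "rebelscan_unknown_term")
  S <- stats::setNames(1, term)
  queue <- term
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]
    for (e in onto$parents_of[[t]] %||% integer()) {
      p <- onto$edges$parent[e]
      cand <- w[[onto$edges$type[e]]] * S[[t]]
      if (is.na(S[p]) || cand > S[[p]]) {
        S[p] <- cand
        queue <- c(queue, p)       # re-propagate improved value upward
      }
    }
  }
  S
}

#' Wang semantic similarity of two GO terms
#'
#' With `S1`, `S2` the [svalues()] mappings of the two terms and `C` their
#' common ancestors (including the terms themselves when shared):
#' `sim = sum_{u in C} (S1(u) + S2(u)) / (sum S1 + sum S2)`.
#' Terms with no shared ancestry (e.g. different GO namespaces) score 0.
#'
#' @param t1,t2 Term ids.
#' @param onto A [go_ontology()].
#' @param w A [wang_weights()].
#' @return Similarity in [0, 1].
#' @export
term_similarity <- function(t1, t2, onto, w = wang_weights()) {
  S1 <- svalues(t1, onto, w)
  S2 <- svalues(t2, onto, w)
  common <- intersect(names(S1), names(S2))
  if (length(common) == 0L) return(0)
  sum(S1[common] + S2[common]) / (sum(S1) + sum(S2))
}

## Aggregation core shared by the domain-pair mean and the worked-example
## check: the plain arithmetic mean over the matrix of all cross-pair
## term similarities.
cross_pair_mean <- function(sim_matrix) mean(sim_matrix)

#' Mean semantic similarity of two annotated domains
#'
#' The mean-semantics-similarity of a domain pair: the average of
#' [term_similarity()] over all `|A| x |B|` cross pairs of the two domains'
#' GO term sets.  With `aggregate = "best_match"` the symmetric best-match
#' average is used instead of the plain mean; with
#' `skip_disjoint = TRUE`, cross pairs with no shared ancestry are dropped
#' from the average rather than contributing 0.
#'
#' @param terms_a,terms_b Non-empty character vectors of GO ids.
#' @param onto A [go_ontology()].
#' @param w A [wang_weights()].
#' @param aggregate `"mean"` (default) or `"best_match"`.
#' @param skip_disjoint Drop zero-ancestry cross pairs from the mean.
#' @return Mean similarity in [0, 1] (`NA` if every pair was dropped).
#' @export
domain_pair_similarity <- function(terms_a, terms_b, onto,
                                   w = wang_weights(),
                                   aggregate = c("mean", "best_match"),
                                   skip_disjoint = FALSE) {
  aggregate <- match.arg(aggregate)
  if (length(terms_a) == 0L || length(terms_b) == 0L)
    abort("domain-pair similarity is undefined for an unannotated domain",
          "rebelscan_unannotated")
  terms_a <- sort(unique(terms_a)); terms_b <- sort(unique(terms_b))
  m <- outer(terms_a, terms_b,
             Vectorize(function(x, y) term_similarity(x, y, onto, w)))
  if (skip_disjoint) {
    shared <- outer(terms_a, terms_b, Vectorize(function(x, y)
      length(intersect(names(svalues(x, onto, w)),
                       names(svalues(y, onto, w)))) > 0L))
    m[!shared] <- NA_real_
    if (all(is.na(m))) return(NA_real_)
  }
  if (aggregate == "mean") mean(m, na.rm = skip_disjoint)
  else mean(c(apply(m, 1, max, na.rm = TRUE),
              apply(m, 2, max, na.rm = TRUE)))
}

#' Grand-average semantic score of one member
#'
#' The GO semantics value attributed to a domain: the grand average of its
#' pairwise mean-semantics-similarities against every other annotated
#' member of the superfamily.  Unannotated members are excluded from both
#' sides.
#'
#' @param member Member id.
#' @param annotations Named list mapping member ids to GO term vectors.
#' @param onto A [go_ontology()].
#' @param w A [wang_weights()].
#' @param ... Passed to [domain_pair_similarity()].
#' @return Grand average in [0, 1].
#' @export
member_semantic_score <- function(member, annotations, onto,
                                  w = wang_weights(), ...) {
  annotated <- names(annotations)[lengths(annotations) > 0L]
  if (!member %in% annotated)
    abort(sprintf("member %s has no GO annotation", member),
          "rebelscan_unannotated")
  others <- sort(setdiff(annotated, member))
  if (length(others) == 0L)
    abort("no other annotated member to compare against",
          "rebelscan_unannotated")
  mean(vapply(others, function(x)
    domain_pair_similarity(annotations[[member]], annotations[[x]],
                           onto, w, ...), numeric(1)))
}

#' Semantic report for a superfamily
#'
#' Computes all pairwise domain mean similarities and every member's grand
#' average, over the annotated members (processed in sorted id order).
#'
#' @inheritParams member_semantic_score
#' @return A list of class `semantic_report`: `pair_means` (symmetric
#'   matrix over annotated members), `member_scores` (named vector),
#'   `annotated` (ids used).
#' @export
semantic_report <- function(annotations, onto, w = wang_weights(), ...) {
  annotated <- sort(names(annotations)[lengths(annotations) > 0L])
  if (length(annotated) < 2L)
    abort("semantic report needs at least 2 annotated members",
          "rebelscan_unannotated")
  n <- length(annotated)
  pm <- matrix(NA_real_, n, n, dimnames = list(annotated, annotated))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pm[i, j] <- pm[j, i] <- domain_pair_similarity(
      annotations[[annotated[i]]], annotations[[annotated[j]]], onto, w, ...)
  }
  scores <- vapply(annotated, function(m) mean(pm[m, -match(m, annotated)],
                                               na.rm = TRUE), numeric(1))
  structure(list(pair_means = pm, member_scores = scores,
                 annotated = annotated),
            class = "semantic_report")
}

#' Contrast structural deviation with functional similarity
#'
#' Joins the structural and semantic layers into the per-member table
#' behind RMSD-versus-GO-semantics scatter plots, with group means over
#' outliers and non-outliers.  Structurally deviant members are expected to
#' show lower semantic scores than the coherent core of the superfamily.
#'
#' @param dev A [deviation_report()].
#' @param sem A [semantic_report()] over (a subset of) the same members.
#' @return A list: `table` (data frame with `member_id`, `mean_rmsd`,
#'   `semantic_score`, `is_outlier`) and `group_means` (named vector with
#'   entries `outliers`, `non_outliers`; `NA` for an empty group).
#' @export
semantics_vs_deviation <- function(dev, sem) {
  if (length(setdiff(sem$annotated, dev$member_ids)) > 0L)
    abort("semantic report covers members absent from the deviation report",
          "rebelscan_id_mismatch")
  ids <- dev$member_ids
  score <- stats::setNames(rep(NA_real_, length(ids)), ids)
  score[sem$annotated] <- sem$member_scores[sem$annotated]
  tab <- data.frame(member_id = ids,
                    mean_rmsd = unname(dev$mean_rmsd[ids]),
                    semantic_score = unname(score),
                    is_outlier = ids %in% dev$outliers,
                    stringsAsFactors = FALSE)
  gm <- c(outliers = if (any(tab$is_outlier))
            mean(tab$semantic_score[tab$is_outlier], na.rm = TRUE)
          else NA_real_,
          non_outliers = if (any(!tab$is_outlier))
            mean(tab$semantic_score[!tab$is_outlier], na.rm = TRUE)
          else NA_real_)
  gm[is.nan(gm)] <- NA_real_
  list(table = tab, group_means = gm)
}
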