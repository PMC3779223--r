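test_that("OBO parsing builds the DAG and skips obsolete terms", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root", "",
    "[Term]", "id: GO:0000002", "name: a", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: b", "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_a: GO:0000001",
    "is_obsolete: true", ""), path)
  onto <- parse_obo(path)
  expect_length(onto$terms, 3L)
  expect_identical(nrow(onto$edges), 2L)
  expect_identical(onto$roots, "GO:0000001")
  expect_false("GO:0000009" %in% onto$terms)
})

test_that("cyclic or dangling ontologies are rejected, odd relationships warned", {
  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "is_a: B", "",
               "[Term]", "id: B", "is_a: A", ""), cyc)
  expect_error(parse_obo(cyc), class = "rebelscan_cyclic_ontology")
  dangling <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "is_a: MISSING", ""), dangling)
  expect_error(parse_obo(dangling), class = "rebelscan_undefined_term")
  odd <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "",
               "[Term]", "id: B", "is_a: A",
               "relationship: regulates A", ""), odd)
  expect_warning(onto <- parse_obo(odd),
                 class = "rebelscan_unknown_relationship")
  expect_identical(nrow(onto$edges), 1L)
})

test_that("OBO files round-trip through write_obo", {
  plan <- generate_toy_ontology(3, 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".obo")
  write_obo(plan$onto, path)
  back <- parse_obo(path)
  expect_identical(back$terms, plan$onto$terms)
  expect_identical(back$edges[order(back$edges$child, back$edges$parent), ],
                   plan$onto$edges[order(plan$onto$edges$child,
                                         plan$onto$edges$parent), ],
                   ignore_attr = TRUE)
})

test_that("S-values follow the Wang recursion on chains and diamonds", {
  ## single step: leaf A under root R
  sib <- toy_sibling_ontology()
  expect_equal(svalues("A", sib), c(A = 1, R = 0.8))
  ## chain A is_a B is_a R: hand propagation 1, 0.8, 0.64
  chain <- toy_chain_ontology()
  s <- svalues("A", chain)
  expect_equal(s[c("A", "B", "R")], c(A = 1, B = 0.8, R = 0.64))
  ## diamond: S(R) = max(0.8 * 0.8, 0.8 * 0.6) = 0.64
  dia <- toy_diamond_ontology()
  sd_ <- svalues("A", dia)
  expect_equal(sd_[["R"]], 0.64)
  expect_equal(sd_[["B"]], 0.8)
  expect_equal(sd_[["C"]], 0.6)
  expect_error(svalues("nope", sib), class = "rebelscan_unknown_term")
})

test_that("term similarity matches hand calculations and is a true similarity", {
  sib <- toy_sibling_ontology()
  ## siblings under one root: (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(term_similarity("A", "B", sib), 0.8 * 2 / 3.6,
               tolerance = 1e-12)
  expect_identical(round(term_similarity("A", "B", sib), 4), 0.4444)
  ## self similarity is exactly 1 for every term of a generated ontology
  plan <- generate_toy_ontology(3, 4, seed = 8)
  for (t in plan$onto$terms)
    expect_identical(term_similarity(t, t, plan$onto), 1)
  ## symmetry and range over all pairs
  terms <- plan$onto$terms
  for (i in seq_along(terms)) for (j in seq_len(i)) {
    v <- term_similarity(terms[i], terms[j], plan$onto)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, term_similarity(terms[j], terms[i], plan$onto))
  }
})

test_that("terms from merged disjoint ontologies score zero", {
  onto <- go_ontology(c("R1", "A1", "R2", "A2"),
                      edges = data.frame(child = c("A1", "A2"),
                                         parent = c("R1", "R2"),
                                         type = "is_a"))
  expect_identical(term_similarity("A1", "A2", onto), 0)
})

test_that("domain-pair similarity is the plain mean over all cross pairs", {
  dia <- toy_diamond_ontology()
  ## identical singleton sets
  expect_equal(domain_pair_similarity("A", "A", dia), 1.0)
  ## 2x2 sets vs a naive double loop
  ta <- c("A", "B"); tb <- c("C", "R")
  naive <- mean(c(term_similarity("A", "C", dia),
                  term_similarity("A", "R", dia),
                  term_similarity("B", "C", dia),
                  term_similarity("B", "R", dia)))
  expect_equal(domain_pair_similarity(ta, tb, dia), naive, tolerance = 1e-12)
  expect_error(domain_pair_similarity(character(), "A", dia),
               class = "rebelscan_unannotated")
})

test_that("the two-level aggregation reproduces the worked 0.4155 average", {
  ## one domain with one term vs one with two: pair similarities 0.077 and
  ## 0.754 average to 0.4155 exactly
  expect_identical(rebelscan:::cross_pair_mean(matrix(c(0.077, 0.754))),
                   0.4155)
})

test_that("member grand averages equal naive recomputation over all pairs", {
  plan <- generate_toy_ontology(3, 3, seed = 13)
  members <- paste0("m", 1:8)
  ann <- plant_annotations(members, "m1", plan, seed = 13)
  sem <- semantic_report(ann, plan$onto)
  for (m in members) {
    naive <- mean(vapply(setdiff(members, m), function(x)
      domain_pair_similarity(ann[[m]], ann[[x]], plan$onto), numeric(1)))
    expect_equal(sem$member_scores[[m]], naive, tolerance = 1e-12)
    expect_equal(member_semantic_score(m, ann, plan$onto), naive,
                 tolerance = 1e-12)
  }
  expect_equal(sem$pair_means, t(sem$pair_means))
  ## unannotated members are excluded from both sides
  ann2 <- ann; ann2$m3 <- character()
  sem2 <- semantic_report(ann2, plan$onto)
  expect_false("m3" %in% sem2$annotated)
  expect_equal(sem2$member_scores[["m1"]],
               mean(vapply(paste0("m", c(2, 4:8)), function(x)
                 domain_pair_similarity(ann2$m1, ann2[[x]], plan$onto),
                 numeric(1))), tolerance = 1e-12)
})

test_that("identical shared annotations never lower a pair mean", {
  dia <- toy_diamond_ontology()
  base <- domain_pair_similarity("B", "C", dia)
  with_shared <- domain_pair_similarity(c("B", "A"), c("C", "A"), dia)
  expect_gt(with_shared, base)
  ## all members sharing one identical term score 1 everywhere
  ann <- stats::setNames(rep(list("A"), 3), paste0("m", 1:3))
  sem <- semantic_report(ann, dia)
  expect_true(all(sem$member_scores == 1))
})

test_that("within-branch term pairs outscore cross-branch pairs in toy ontologies", {
  for (seed in c(3, 17)) {
    plan <- generate_toy_ontology(3, 3, seed = seed)
    branch_of <- rep(seq_along(plan$branch_terms),
                     lengths(plan$branch_terms))
    terms <- unlist(plan$branch_terms)
    sims <- outer(terms, terms, Vectorize(function(x, y)
      term_similarity(x, y, plan$onto)))
    same <- outer(branch_of, branch_of, `==`) & upper.tri(sims)
    cross <- outer(branch_of, branch_of, `!=`) & upper.tri(sims)
    expect_gt(min(sims[same]), max(sims[cross]))
  }
})

test_that("branch-disjoint outlier annotations depress outlier semantic scores", {
  sf <- make_superfamily(canonical_spec(19))
  ens <- multiple_superpose(sf$alignment, sf$structures)
  dev <- deviation_report(sf$alignment, sf$structures, ens,
                          tm_scope = "candidates")
  plan <- generate_toy_ontology(2, 3, seed = 19)
  ann <- plant_annotations(names(sf$structures), sf$truth$planted_outliers,
                           plan, seed = 19)
  sem <- semantic_report(ann, plan$onto)
  sv <- semantics_vs_deviation(dev, sem)
  expect_identical(sv$table$member_id, dev$member_ids)
  out_scores <- sv$table$semantic_score[sv$table$is_outlier]
  non_scores <- sv$table$semantic_score[!sv$table$is_outlier]
  expect_true(all(vapply(out_scores, function(o) all(o < non_scores),
                         logical(1))))
  expect_lt(sv$group_means[["outliers"]], sv$group_means[["non_outliers"]])
  ## no-outlier report leaves the outlier group mean missing
  dev0 <- dev; dev0$outliers <- character()
  sv0 <- semantics_vs_deviation(dev0, sem)
  expect_true(is.na(sv0$group_means[["outliers"]]))
})
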