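write_toy_obo <- function(lines, path = tempfile(fileext = ".obo")) {
  writeLines(c("format-version: 1.2", "", lines), path)
  path
}

test_that("read_obo parses terms and is_a edges, skipping obsolete terms", {
  f <- write_toy_obo(c(
    "[Term]", "id: T:1", "name: root", "namespace: mf", "",
    "[Term]", "id: T:2", "name: child two", "namespace: mf",
    "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: child three", "namespace: mf",
    "is_a: T:1", "",
    "[Term]", "id: T:9", "name: gone", "namespace: mf", "is_a: T:1",
    "is_obsolete: true", "",
    "[Typedef]", "id: part_of"))
  ont <- read_obo(f)
  expect_equal(nrow(ont$terms), 3L)
  expect_equal(nrow(ont$edges), 2L)
  expect_false("T:9" %in% ont$terms$term)
  expect_equal(unname(ont$roots), "T:1")
})

test_that("cyclic ontologies are rejected with a named cycle member", {
  f <- write_toy_obo(c(
    "[Term]", "id: C:1", "name: a", "namespace: mf", "is_a: C:2", "",
    "[Term]", "id: C:2", "name: b", "namespace: mf", "is_a: C:1"))
  expect_error(read_obo(f), "cycle.*C:[12]")
})

test_that("term depth is the longest root path; level the shortest", {
  d <- diamond_ontology()   # root -> a -> c, root -> c, root -> b
  expect_equal(unname(term_depth(d, "D:root")), 0L)
  expect_equal(unname(term_depth(d, "D:a")), 1L)
  expect_equal(unname(term_depth(d, "D:c")), 2L)   # longest path wins
  expect_equal(d$terms$level[d$terms$term == "D:c"], 1L)  # shortest
  expect_error(term_depth(d, "D:missing"), "unknown term")

  # chain root -> a -> b
  chain <- ontology_from_tables(
    tibble::tibble(term = c("r", "a", "b"), name = c("r", "a", "b"),
                   namespace = "mf"),
    tibble::tibble(child = c("a", "b"), parent = c("r", "a")))
  expect_equal(unname(term_depth(chain, "b")), 2L)
})

test_that("annotation propagation is the idempotent ancestor closure", {
  toy <- make_toy_ontology(n_branches = 2L, depth = 3L, pop = 24L, seed = 2L)
  ann <- toy$annotations
  expect_true(nrow(ann$propagated) >= nrow(ann$direct))
  # closure: every ancestor of an annotated term is annotated
  anc <- toy$ontology$ancestors
  by_id <- split(ann$propagated$term, ann$propagated$id)
  for (id in names(by_id)[1:5]) {
    terms <- by_id[[id]]
    expect_setequal(unique(unlist(anc[terms])), terms)  # idempotent
  }
  # unknown annotation targets are dropped with a warning
  expect_warning(
    build_annotations(tibble::tibble(id = c("P1", "P2"),
                                     term = c("TOY:0000001", "NOPE:1")),
                      toy$ontology),
    "unknown terms")
})

test_that("information content counts propagated annotations", {
  toy <- make_toy_ontology(n_branches = 2L, depth = 2L, pop = 8L, seed = 1L)
  ont <- toy$ontology; ann <- toy$annotations
  root <- unname(ont$roots)
  expect_equal(unname(information_content(ann, root)), 0)
  # balanced round-robin: each of 4 leaves holds 2 of 8 proteins
  leaves <- ont$terms$term[ont$terms$depth == 2L]
  ics <- information_content(ann, leaves)
  expect_equal(unname(ics), rep(log(4), 4L))
  # 1-of-8 term: add a child under a leaf annotated to one protein
  one <- information_content(
    build_annotations(
      tibble::tibble(id = sprintf("P%04d", 1:8),
                     term = c("TOY:0000003", rep(ont$roots, 7L))),
      ont),
    "TOY:0000003")
  expect_equal(unname(one), log(8))
})

test_that("Lin similarity: self, root-only ancestor, and the sibling fixture", {
  toy <- make_toy_ontology(n_branches = 2L, depth = 2L, pop = 8L, seed = 1L)
  ont <- toy$ontology; ann <- toy$annotations
  leaves <- sort(ont$terms$term[ont$terms$depth == 2L])
  mid <- sort(ont$terms$term[ont$terms$depth == 1L])
  # siblings under a parent with IC log 2, each child IC log 4 -> 0.5
  expect_equal(lin_similarity(ont, ann, leaves[1], leaves[2]), 0.5)
  # self-similarity is 1 when IC > 0
  expect_equal(lin_similarity(ont, ann, leaves[1], leaves[1]), 1)
  # only common ancestor is the root -> 0
  expect_equal(lin_similarity(ont, ann, mid[1], mid[2]), 0)
  expect_equal(lin_similarity(ont, ann, leaves[1], leaves[3]), 0)
  # symmetry and range
  s <- lin_similarity(ont, ann, leaves[1], mid[1])
  expect_equal(s, lin_similarity(ont, ann, mid[1], leaves[1]))
  expect_true(s >= 0 && s <= 1)
  # resnik variant returns IC(MICA)
  expect_equal(lin_similarity(ont, ann, leaves[1], leaves[2],
                              measure = "resnik"), log(2))
})

test_that("Lin similarity decays as the MICA moves toward the root", {
  # chain r -> a -> b -> c with strictly shrinking annotation counts:
  # sim(c, x) must not increase as x walks from c's sibling side up to r
  chain <- ontology_from_tables(
    tibble::tibble(term = c("r", "a", "b", "c"), name = c("r", "a", "b", "c"),
                   namespace = "mf"),
    tibble::tibble(child = c("a", "b", "c"), parent = c("r", "a", "b")))
  mapping <- tibble::tibble(
    id = sprintf("P%02d", 1:8),
    term = c(rep("c", 1), rep("b", 1), rep("a", 2), rep("r", 4)))
  ann <- build_annotations(mapping, chain)
  sims <- vapply(c("c", "b", "a", "r"), function(t)
    lin_similarity(chain, ann, "c", t), numeric(1))
  expect_true(all(diff(sims) <= 1e-12))
})

test_that("hypergeometric enrichment matches closed forms and brute force", {
  # population 20, term T holds 5; study = exactly those 5 -> 1/C(20,5)
  ont <- ontology_from_tables(
    tibble::tibble(term = c("r", "T", "U"), name = c("r", "rna binding", "u"),
                   namespace = "mf"),
    tibble::tibble(child = c("T", "U"), parent = c("r", "r")))
  ids <- sprintf("P%02d", 1:20)
  mapping <- tibble::tibble(
    id = ids, term = c(rep("T", 5), rep("U", 10), rep("r", 5)))
  ann <- build_annotations(mapping, ont)
  enr <- enrich_terms(ann, ids[1:5], ont)
  expect_equal(enr$p_raw[enr$term == "T"], 1 / choose(20, 5))
  # a term annotated to the whole population is never enriched
  expect_equal(enr$p_raw[enr$term == "r"], 1)
  # brute-force tail enumeration for every reported term
  for (i in seq_len(nrow(enr))) {
    K <- enr$pop_count[i]; n <- enr$study_n[i]; N <- enr$pop_n[i]
    x <- enr$study_count[i]
    sup <- max(0, K + n - N):min(K, n)
    pmf <- choose(K, sup) * choose(N - K, n - sup) / choose(N, n)
    expect_equal(enr$p_raw[i], sum(pmf[sup >= x]), tolerance = 1e-12)
  }
  # Bonferroni: m tested terms, capped at 1
  m <- nrow(enr)
  expect_equal(enr$p_bonferroni, pmin(1, m * enr$p_raw))
  expect_equal(enr$p_bonferroni[enr$term == "r"], 1)
  expect_error(enrich_terms(ann, character(0), ont), "empty study")
  expect_warning(enrich_terms(ann, c(ids[1:5], "GHOST"), ont),
                 "not in the annotated population")
})

test_that("filter_terms applies conjunctive depth/precision/p/text filters", {
  ont <- ontology_from_tables(
    tibble::tibble(term = c("r", "T", "U"),
                   name = c("root", "RNA binding", "unrelated"),
                   namespace = "mf"),
    tibble::tibble(child = c("T", "U"), parent = c("r", "r")))
  ids <- sprintf("P%02d", 1:20)
  ann <- build_annotations(
    tibble::tibble(id = ids, term = c(rep("T", 5), rep("U", 15))), ont)
  enr <- enrich_terms(ann, ids[1:5], ont)
  expect_equal(nrow(filter_terms(enr)), nrow(enr))           # identity
  expect_equal(nrow(filter_terms(enr, p_cut = 0)), 0L)       # empty
  hit <- filter_terms(enr, text = "rna")
  expect_equal(hit$term, "T")                                # case-insensitive
  expect_true(all(filter_terms(enr, min_depth = 1L)$depth >= 1L))
})

test_that("similarity clustering: thresholds, refinement, coverage", {
  toy <- make_toy_ontology(n_branches = 2L, depth = 2L, pop = 8L, seed = 1L)
  ont <- toy$ontology; ann <- toy$annotations
  study <- toy$proteins
  enr <- suppressWarnings(enrich_terms(ann, study, ont))

  # threshold above 1: every term is its own singleton cluster
  cl_hi <- cluster_terms(enr, ont, ann, sim_threshold = 1.01)
  expect_equal(nrow(cl_hi$clusters), nrow(enr))
  # threshold 0: a single cluster per namespace
  cl_lo <- cluster_terms(enr, ont, ann, sim_threshold = 0)
  expect_equal(nrow(cl_lo$clusters), 1L)

  # at 0.5 the sibling leaves join their branch, the other branch is apart
  cl <- cluster_terms(enr, ont, ann, sim_threshold = 0.5)
  memb <- cl$assignment
  leaves <- sort(ont$terms$term[ont$terms$depth == 2L])
  expect_equal(memb$cluster[memb$term == leaves[1]],
               memb$cluster[memb$term == leaves[2]])
  expect_false(memb$cluster[memb$term == leaves[1]] ==
                 memb$cluster[memb$term == leaves[3]])

  # refinement: clusters at a higher threshold subdivide lower-threshold ones
  for (tau in c(0.2, 0.5, 0.8)) {
    coarse <- cluster_terms(enr, ont, ann, sim_threshold = tau)$assignment
    fine <- cluster_terms(enr, ont, ann, sim_threshold = tau + 0.15)$assignment
    joined <- dplyr::inner_join(coarse, fine, by = "term",
                                suffix = c("_c", "_f"))
    split_map <- dplyr::distinct(joined, .data$cluster_f, .data$cluster_c)
    expect_equal(nrow(split_map), length(unique(split_map$cluster_f)))
  }

  # coverage counts distinct proteins; duplicating a member changes nothing
  cov1 <- cl$clusters$coverage_count[1L]
  dup <- dplyr::bind_rows(enr, enr[enr$term %in% cl$clusters$members[[1L]], ][1L, ])
  attr(dup, "study") <- attr(enr, "study")
  cl_dup <- cluster_terms(dup, ont, ann, sim_threshold = 0.5)
  expect_equal(cl_dup$clusters$coverage_count[1L], cov1)

  # coverage = distinct study proteins annotated to >= 1 member term
  members <- cl$clusters$members[[1L]]
  prop <- ann$propagated
  manual <- length(unique(prop$id[prop$term %in% members & prop$id %in% study]))
  expect_equal(cl$clusters$coverage_count[1L], manual)
})

test_that("OBO/GAF round-trip preserves the toy ontology and annotations", {
  toy <- make_toy_ontology(n_branches = 3L, depth = 2L, pop = 12L, seed = 4L)
  obo <- tempfile(fileext = ".obo"); gaf <- tempfile(fileext = ".gaf")
  write_obo(toy$ontology, obo)
  write_gaf(toy$mapping, gaf)
  ont2 <- read_obo(obo)
  expect_setequal(ont2$terms$term, toy$ontology$terms$term)
  expect_equal(dplyr::arrange(ont2$edges[1:2], child, parent),
               dplyr::arrange(toy$ontology$edges[1:2], child, parent))
  back <- read_gaf(gaf)
  expect_setequal(paste(back$id, back$term),
                  paste(toy$mapping$id, toy$mapping$term))
})
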