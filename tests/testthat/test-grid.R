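make_fake_results <- function(n_pos_sig, n_neg_sig, n = 10L) {
  dir <- c(rep("positive_up", n_pos_sig), rep("negative_up", n_neg_sig),
           rep("none", n - n_pos_sig - n_neg_sig))
  tibble::tibble(
    scale = sprintf("s%02d", seq_len(n)),
    fisher_p = ifelse(dir == "none", 0.5, 1e-8),
    direction = dir
  )
}

test_that("consensus_call implements the four-state majority rule", {
  expect_equal(consensus_call(make_fake_results(10, 0))$state,
               "POSITIVE_ENRICHED")
  expect_equal(consensus_call(make_fake_results(0, 10))$state,
               "NEGATIVE_ENRICHED")
  expect_equal(consensus_call(make_fake_results(0, 0))$state,
               "NON_SIGNIFICANT")
  expect_equal(consensus_call(make_fake_results(5, 0))$state,  # below majority
               "NON_SIGNIFICANT")
  expect_equal(consensus_call(make_fake_results(6, 0))$state,
               "POSITIVE_ENRICHED")
  # strong overlap overrides any counts
  expect_equal(consensus_call(make_fake_results(10, 0),
                              overlap_jaccard = 0.9)$state,
               "NOT_CALCULABLE")
  expect_error(consensus_call(make_fake_results(0, 0)[0, ]), "empty")
})

test_that("stricter p_cut never converts NON_SIGNIFICANT into enrichment", {
  withr::with_seed(31, {
    for (i in 1:20) {
      res <- tibble::tibble(
        scale = sprintf("s%02d", 1:10),
        fisher_p = 10^stats::runif(10, -9, 0),
        direction = sample(c("positive_up", "negative_up"), 10, TRUE)
      )
      cuts <- sort(10^stats::runif(4, -8, -1), decreasing = TRUE)
      states <- vapply(cuts, function(pc) {
        consensus_call(res, p_cut = pc)$state
      }, character(1))
      for (k in seq_along(states)[-1]) {
        if (states[k - 1] == "NON_SIGNIFICANT") {
          expect_equal(states[k], "NON_SIGNIFICANT")
        }
      }
    }
  })
})

test_that("run_grid enumerates ordered cells and flags identical datasets", {
  reg <- synth_registry(n_groups = 7L, n_scales = 10L)
  withr::with_seed(32, {
    sets <- dplyr::bind_rows(lapply(1:3, function(i) {
      make_biased_dataset(n = 20L, seed = 100L + i,
                          dataset = paste0("ds", i),
                          group = if (i == 1L) "positive" else "negative")
    }))
  })
  g <- run_grid(sets, reg, seed = 1L)
  expect_s3_class(g, "clever_grid")
  expect_equal(nrow(g$cells), 3L * 2L * 7L)  # ordered pairs x properties
  expect_equal(nrow(glance(g)), 1L)
  expect_equal(glance(g)$n_cells, 42L)

  # identical datasets: jaccard 1 -> every cell NOT_CALCULABLE
  twin <- sets[sets$dataset == "ds1", ]
  twin$dataset <- "twin"; twin$group <- "negative"
  g2 <- run_grid(dplyr::bind_rows(sets[sets$dataset == "ds1", ], twin),
                 reg, seed = 1L)
  expect_true(all(g2$cells$state == "NOT_CALCULABLE"))
  expect_true(all(g2$cells$overlap_jaccard == 1))

  expect_error(run_grid(sets[sets$dataset == "ds1", ], reg),
               "at least two datasets")
})

test_that("exchanging positive/negative roles mirrors every cell", {
  reg <- synth_registry(n_groups = 3L, n_scales = 10L)
  a <- make_biased_dataset(n = 60L, scale = reg[reg$scale == "SG01S01", ],
                           effect = 1.5, seed = 41L, dataset = "a",
                           group = "positive")
  b <- make_biased_dataset(n = 60L, seed = 42L, dataset = "b",
                           group = "negative")
  g <- run_grid(dplyr::bind_rows(a, b), reg, seed = 7L)
  ab <- g$cells[g$cells$positive == "a", ]
  ba <- g$cells[g$cells$positive == "b", ]
  ba <- ba[match(ab$property, ba$property), ]
  mirror <- c(POSITIVE_ENRICHED = "NEGATIVE_ENRICHED",
              NEGATIVE_ENRICHED = "POSITIVE_ENRICHED",
              NON_SIGNIFICANT = "NON_SIGNIFICANT",
              NOT_CALCULABLE = "NOT_CALCULABLE")
  expect_equal(unname(mirror[ab$state]), ba$state)
  expect_equal(ab$n_significant_pos, ba$n_significant_neg)

  # per-scale mirror: auc complements, p-values identical
  ps_ab <- g$per_scale[g$per_scale$positive == "a", ]
  ps_ba <- g$per_scale[g$per_scale$positive == "b", ]
  ps_ba <- ps_ba[match(ps_ab$scale, ps_ba$scale), ]
  expect_identical(ps_ab$auc + ps_ba$auc, rep(1, nrow(ps_ab)))
  expect_equal(ps_ab$fisher_p, ps_ba$fisher_p)

  # and the mirror equals an actual recomputation with roles exchanged
  a2 <- a; a2$group <- "negative"
  b2 <- b; b2$group <- "positive"
  g_swap <- run_grid(dplyr::bind_rows(b2, a2), reg, seed = 7L)
  sw <- g_swap$cells[g_swap$cells$positive == "b", ]
  sw <- sw[match(ab$property, sw$property), ]
  expect_equal(ba$state, sw$state)
})

test_that("a targeted compositional bias lights up only its property group", {
  # mild tilt: selectivity only holds in the near-linear regime of the
  # exponential tilt, where a scale orthogonal to the target sees no
  # composition shift; strong tilts leak into every group through the
  # nonlinear terms of exp(effect * z)
  reg <- synth_registry(n_groups = 7L, n_scales = 10L)
  target <- reg[reg$scale == "SG03S01", ]
  pos <- make_biased_dataset(n = 300L, scale = target, effect = 0.3,
                             seed = 51L, dataset = "bias", group = "positive")
  neg <- make_biased_dataset(n = 300L, effect = 0, seed = 52L,
                             dataset = "null", group = "negative")
  g <- run_grid(dplyr::bind_rows(pos, neg), reg, seed = 3L)
  cells <- g$cells[g$cells$positive == "bias", ]
  expect_equal(cells$state[cells$property == "PROP03"], "POSITIVE_ENRICHED")
  others <- cells$state[cells$property != "PROP03"]
  expect_gte(sum(others == "NON_SIGNIFICANT"), 5L)
})

test_that("identical inputs, config and seed give identical grids", {
  reg <- synth_registry(n_groups = 2L, n_scales = 10L)
  ds <- dplyr::bind_rows(
    make_biased_dataset(n = 30L, seed = 61L, dataset = "x"),
    make_biased_dataset(n = 30L, seed = 62L, dataset = "y",
                        group = "negative"))
  g1 <- run_grid(ds, reg, seed = 5L)
  g2 <- run_grid(ds, reg, seed = 5L)
  expect_identical(g1$cells, g2$cells)
  expect_identical(g1$per_scale, g2$per_scale)
})

test_that("best_scales returns the minimum-Fisher-p scale per property", {
  reg <- synth_registry(n_groups = 2L, n_scales = 4L)
  ds <- dplyr::bind_rows(
    make_biased_dataset(n = 40L, scale = reg[reg$scale == "SG01S01", ],
                        effect = 2, seed = 71L, dataset = "x"),
    make_biased_dataset(n = 40L, seed = 72L, dataset = "y",
                        group = "negative"))
  g <- run_grid(ds, reg, seed = 2L)
  bs <- best_scales(g, positive = "x", negative = "y")
  expect_equal(nrow(bs), 2L)
  for (p in bs$property) {
    sub <- g$per_scale[g$per_scale$property == p &
                         g$per_scale$positive == "x", ]
    expect_equal(bs$fisher_p[bs$property == p], min(sub$fisher_p))
  }
})
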