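# The multi-dataset comparison grid: every ordered dataset pair is compared
# along every property group; the ~10 per-scale Fisher tests of a group are
# collated into one of four consensus states, rendered microarray-style.

GRID_STATES <- c("POSITIVE_ENRICHED", "NEGATIVE_ENRICHED",
                 "NON_SIGNIFICANT", "NOT_CALCULABLE")

#' Consensus call for one dataset pair x property group
#'
#' Counts member scales whose one-sided Fisher p-value falls below `p_cut`
#' in each direction. The cell state is `POSITIVE_ENRICHED` when at least
#' `majority` scales are significant toward the positive set and fewer than
#' `majority` toward the negative set (and symmetrically for
#' `NEGATIVE_ENRICHED`); otherwise `NON_SIGNIFICANT`. A pair whose sequence
#' overlap exceeds `max_overlap` is `NOT_CALCULABLE` regardless of counts,
#' because overlapping sets make the score distributions non-independent.
#'
#' @param results Per-scale discrimination tibble (one property group, one
#'   dataset pair), as returned by [discriminate_scales()].
#' @param overlap_jaccard Sequence Jaccard index of the pair.
#' @param p_cut Per-scale Fisher significance cutoff (default `1e-5`).
#' @param majority Minimum number of significant scales for a consensus
#'   (default 6 of 10).
#' @param max_overlap Jaccard threshold above which the cell is
#'   `NOT_CALCULABLE` (default 0.2).
#' @return A one-row tibble: `state`, `n_significant_pos`,
#'   `n_significant_neg`, `n_scales`, `min_fisher_p`, `best_scale`,
#'   `overlap_jaccard`.
#' @export
consensus_call <- function(results, overlap_jaccard = 0, p_cut = 1e-5,
                           majority = 6L, max_overlap = 0.2) {
  if (nrow(results) == 0L) stop("empty result list", call. = FALSE)
  sig <- results$fisher_p < p_cut
  n_pos <- sum(sig & results$direction == "positive_up")
  n_neg <- sum(sig & results$direction == "negative_up")
  state <- if (overlap_jaccard > max_overlap) {
    "NOT_CALCULABLE"
  } else if (n_pos >= majority && n_neg < majority) {
    "POSITIVE_ENRICHED"
  } else if (n_neg >= majority && n_pos < majority) {
    "NEGATIVE_ENRICHED"
  } else {
    "NON_SIGNIFICANT"
  }
  best <- which.min(results$fisher_p)
  tibble::tibble(
    state = state, n_significant_pos = n_pos, n_significant_neg = n_neg,
    n_scales = nrow(results), min_fisher_p = results$fisher_p[best],
    best_scale = results$scale[best], overlap_jaccard = overlap_jaccard
  )
}

.mirror_state <- function(state) {
  dplyr::case_match(state,
    "POSITIVE_ENRICHED" ~ "NEGATIVE_ENRICHED",
    "NEGATIVE_ENRICHED" ~ "POSITIVE_ENRICHED",
    .default = state
  )
}

.mirror_direction <- function(direction) {
  dplyr::case_match(direction,
    "positive_up" ~ "negative_up",
    "negative_up" ~ "positive_up",
    .default = direction
  )
}

#' Run the full multi-dataset comparison grid
#'
#' Scores every dataset against every scale, runs the discrimination
#' statistics for each unordered dataset pair x scale, and collates each
#' property group into a consensus cell. Both ordered cells of a pair are
#' reported; exchanging the positive/negative roles mirrors the state
#' (`POSITIVE_ENRICHED` <-> `NEGATIVE_ENRICHED`), flips the per-scale
#' direction and maps AUC to 1 - AUC, with identical p-values.
#'
#' @param data Combined protein tibble holding >= 2 datasets.
#' @param scales Tidy scale tibble (default: the full built-in registry).
#' @param p_cut,majority,max_overlap See [consensus_call()].
#' @param window Scoring window ([score_sequences()]).
#' @param cv_folds Cross-validation folds for per-scale accuracy.
#' @param seed Integer seed controlling fold assignment; fixed seed +
#'   identical inputs give identical grids.
#' @return A `clever_grid` object: list with `cells` (one row per ordered
#'   pair x property), `per_scale` (full per-scale statistics) and `config`.
#' @examples
#' \donttest{
#' pos <- make_biased_dataset(n = 60, scale = "KYTJ820101", effect = 2,
#'                            seed = 1, dataset = "pos", group = "positive")
#' neg <- make_biased_dataset(n = 60, effect = 0, seed = 2,
#'                            dataset = "neg", group = "negative")
#' g <- run_grid(dplyr::bind_rows(pos, neg), seed = 1)
#' tidy(g)
#' }
#' @export
run_grid <- function(data, scales = scale_registry(), p_cut = 1e-5,
                     majority = 6L, max_overlap = 0.2, window = 7L,
                     cv_folds = 10L, seed = 1L) {
  ds <- unique(data$dataset)
  if (length(ds) < 2L) {
    stop("need at least two datasets to build a comparison grid",
         call. = FALSE)
  }
  scores <- score_sequences(data, scales, window = window)
  pairs <- utils::combn(ds, 2L, simplify = FALSE)

  per_scale <- purrr::imap_dfr(pairs, function(p, k) {
    sub <- scores[scores$dataset %in% p, ]
    sub$group <- ifelse(sub$dataset == p[1L], "positive", "negative")
    res <- discriminate_scales(sub, cv_folds = cv_folds,
                               seed = seed + 1000L * k)
    res$positive <- p[1L]; res$negative <- p[2L]
    res
  })

  ov <- overlap_report(data)
  ov_key <- stats::setNames(ov$jaccard,
                            paste(ov$dataset_a, ov$dataset_b, sep = "\r"))
  pair_overlap <- function(x, y) {
    j <- ov_key[paste(x, y, sep = "\r")]
    if (is.na(j)) j <- ov_key[paste(y, x, sep = "\r")]
    unname(j)
  }

  cells <- per_scale |>
    dplyr::group_by(.data$positive, .data$negative, .data$property) |>
    dplyr::group_modify(function(g, key) {
      consensus_call(g, pair_overlap(key$positive, key$negative),
                     p_cut = p_cut, majority = majority,
                     max_overlap = max_overlap)
    }) |>
    dplyr::ungroup()

  # mirrored ordered cells: swap roles of the pair
  cells_m <- cells |>
    dplyr::mutate(
      tmp = .data$positive, positive = .data$negative, negative = .data$tmp,
      state = .mirror_state(.data$state),
      tmp_n = .data$n_significant_pos,
      n_significant_pos = .data$n_significant_neg,
      n_significant_neg = .data$tmp_n
    ) |>
    dplyr::select(-"tmp", -"tmp_n")
  per_scale_m <- per_scale |>
    dplyr::mutate(
      tmp = .data$positive, positive = .data$negative, negative = .data$tmp,
      tmp_a = .data$a, a = .data$c, c = .data$tmp_a,
      tmp_b = .data$b, b = .data$d, d = .data$tmp_b,
      tmp_n = .data$n_pos, n_pos = .data$n_neg, n_neg = .data$tmp_n,
      direction = .mirror_direction(.data$direction),
      auc = 1 - .data$auc
    ) |>
    dplyr::select(-"tmp", -"tmp_a", -"tmp_b", -"tmp_n")

  all_cells <- dplyr::bind_rows(cells, cells_m) |>
    dplyr::arrange(.data$positive, .data$negative, .data$property)
  all_scale <- dplyr::bind_rows(per_scale, per_scale_m) |>
    dplyr::arrange(.data$positive, .data$negative, .data$property,
                   .data$scale)

  structure(
    list(
      cells = all_cells,
      per_scale = all_scale[c("positive", "negative", "property", "scale",
                              "n_pos", "n_neg", "threshold", "a", "b", "c",
                              "d", "direction", "fisher_p", "mww_p", "auc",
                              "cv_accuracy")],
      config = list(p_cut = p_cut, majority = majority,
                    max_overlap = max_overlap, window = window,
                    cv_folds = cv_folds, seed = seed,
                    datasets = ds, n_scales = length(unique(scales$scale)))
    ),
    class = "clever_grid"
  )
}

#' @export
print.clever_grid <- function(x, ...) {
  cat("<clever_grid> ", length(x$config$datasets), " datasets, ",
      length(unique(x$cells$property)), " properties, ",
      nrow(x$cells), " ordered cells\n", sep = "")
  print(table(x$cells$state))
  invisible(x)
}

#' @describeIn run_grid Tidy cell table of a grid (one row per ordered pair
#'   x property).
#' @param x A `clever_grid` object.
#' @param ... Unused.
#' @export
tidy.clever_grid <- function(x, ...) x$cells

#' @describeIn run_grid One-row grid summary (dataset/pair/cell counts and
#'   state tallies).
#' @export
glance.clever_grid <- function(x, ...) {
  st <- table(factor(x$cells$state, levels = GRID_STATES))
  tibble::tibble(
    n_datasets = length(x$config$datasets),
    n_properties = length(unique(x$cells$property)),
    n_cells = nrow(x$cells),
    n_positive_enriched = as.integer(st[["POSITIVE_ENRICHED"]]),
    n_negative_enriched = as.integer(st[["NEGATIVE_ENRICHED"]]),
    n_non_significant = as.integer(st[["NON_SIGNIFICANT"]]),
    n_not_calculable = as.integer(st[["NOT_CALCULABLE"]])
  )
}

#' @describeIn run_grid Microarray-style tile plot of the grid (positive
#'   set on the vertical axis, negative on the horizontal; green = positive
#'   enriched, red = negative enriched, yellow = non-significant, grey =
#'   not calculable).
#' @param object A `clever_grid` object.
#' @export
autoplot.clever_grid <- function(object, ...) {
  cols <- c(POSITIVE_ENRICHED = "#2ca02c", NEGATIVE_ENRICHED = "#d62728",
            NON_SIGNIFICANT = "#ffd92f", NOT_CALCULABLE = "grey70")
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(x = .data$negative, y = .data$positive,
                               fill = .data$state)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = cols, drop = FALSE) +
    ggplot2::facet_wrap(~property) +
    ggplot2::labs(x = "negative set", y = "positive set", fill = "state") +
    ggplot2::theme_minimal()
}

#' Best-performing scale per property of a grid cell pair
#'
#' The scale with the smallest Fisher p-value within each property group,
#' for a given ordered dataset pair — the hand-off from the grid detail
#' view to the box-plot view.
#'
#' @param grid A `clever_grid`.
#' @param positive,negative Dataset names selecting the ordered pair
#'   (defaults: first ordered pair in the grid).
#' @return A tibble: `property`, `scale`, `fisher_p`, `mww_p`, `auc`.
#' @export
best_scales <- function(grid, positive = NULL, negative = NULL) {
  ps <- grid$per_scale
  if (is.null(positive)) positive <- ps$positive[1L]
  if (is.null(negative)) negative <- ps$negative[ps$positive == positive][1L]
  ps |>
    dplyr::filter(.data$positive == !!positive,
                  .data$negative == !!negative) |>
    dplyr::group_by(.data$property) |>
    dplyr::slice_min(.data$fisher_p, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("property", "scale", "fisher_p", "mww_p", "auc")
}
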