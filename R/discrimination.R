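# Per-scale binary discrimination statistics: one-sided Fisher exact test,
# rank-based AUC, Mann-Whitney-Wilcoxon test, and cross-validated accuracy
# of the median-threshold classifier.

#' One-sided Fisher exact test in the direction of the observed imbalance
#'
#' For a 2x2 table with rows = (positive set, negative set) and columns =
#' (score above threshold, score at/below threshold), returns the one-sided
#' hypergeometric tail probability under fixed margins: `P(X >= a)` when the
#' positive set has the larger above-threshold proportion, `P(X <= a)`
#' otherwise. A zero margin yields p = 1 by convention.
#'
#' @param a,b Above/below counts in the positive set.
#' @param c,d Above/below counts in the negative set.
#' @return The one-sided p-value in (0, 1].
#' @examples
#' fisher_exact_onesided(3, 0, 0, 3)  # 1 / choose(6, 3) = 0.05
#' @export
fisher_exact_onesided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  # X = above-threshold count in the positive set, hypergeometric with
  # white = a + c, black = b + d, draws = a + b.
  if (a / (a + b) >= c / (c + d)) {
    phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
  } else {
    phyper(a, a + c, b + d, a + b, lower.tail = TRUE)
  }
}

#' Area under the ROC curve from two score groups
#'
#' Rank-based (Mann-Whitney U) AUC with half credit for ties:
#' `AUC = U / (n_pos * n_neg)`. Values above 0.5 mean positive scores are
#' stochastically larger.
#'
#' @param pos,neg Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(pos, neg) {
  stopifnot(length(pos) >= 1L, length(neg) >= 1L)
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nn)
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Exact null distribution (via the Wilcoxon U distribution) when both
#' groups have at most 20 observations and the pooled scores contain no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction. Degenerate input (all pooled values identical)
#' returns p = 1.
#'
#' @param pos,neg Numeric score vectors.
#' @return Two-sided p-value in (0, 1].
#' @export
mww_test <- function(pos, neg) {
  stopifnot(length(pos) >= 1L, length(neg) >= 1L)
  pooled <- c(pos, neg)
  if (length(unique(pooled)) == 1L) return(1)
  n1 <- length(pos); n2 <- length(neg)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n1 <= 20L && n2 <= 20L) {
    p <- if (u > n1 * n2 / 2) {
      2 * pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * pwilcox(u, n1, n2)
    }
    return(min(1, p))
  }
  n <- n1 + n2
  tab <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- u - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
  min(1, 2 * pnorm(-abs(z)))
}

#' ROC curve points
#'
#' Step-curve coordinates (false-positive rate, true-positive rate) for the
#' "score above threshold calls positive" classifier, sweeping the threshold
#' over the observed scores.
#'
#' @param pos,neg Numeric score vectors.
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(pos, neg) {
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(pos >= t), numeric(1))
  )
}

# Stratified k-fold cross-validated accuracy of the pooled-median-threshold
# classifier. Fold assignment is drawn from the current RNG state; callers
# that need reproducibility wrap the call in withr::with_seed().
.cv_accuracy <- function(pos, neg, folds = 10L) {
  n1 <- length(pos); n2 <- length(neg)
  k <- max(2L, min(folds, n1, n2))
  f1 <- sample(rep_len(seq_len(k), n1))
  f2 <- sample(rep_len(seq_len(k), n2))
  acc <- vapply(seq_len(k), function(i) {
    trp <- pos[f1 != i]; trn <- neg[f2 != i]
    tep <- pos[f1 == i]; ten <- neg[f2 == i]
    thr <- median(c(trp, trn))
    pos_up <- mean(trp > thr) >= mean(trn > thr)
    if (pos_up) {
      (sum(tep > thr) + sum(ten <= thr)) / (length(tep) + length(ten))
    } else {
      (sum(tep <= thr) + sum(ten > thr)) / (length(tep) + length(ten))
    }
  }, numeric(1))
  mean(acc)
}

#' Full discrimination analysis of one score pair
#'
#' Thresholds the pooled scores at their median, builds the 2x2
#' above/below contingency table, and reports the one-sided Fisher p-value
#' (in the observed direction), the two-sided Mann-Whitney-Wilcoxon
#' p-value, the rank-based AUC and the stratified 10-fold cross-validated
#' accuracy of the median-threshold classifier. When the pooled scores are
#' all equal the direction is `"none"` and both p-values are 1.
#'
#' @param pos,neg Numeric score vectors (positive / negative set).
#' @param scale Scale name carried into the output.
#' @param cv_folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment (`NULL` = current RNG).
#' @return A one-row tibble: `scale`, `n_pos`, `n_neg`, `threshold`,
#'   `a`, `b`, `c`, `d`, `direction` (`"positive_up"`, `"negative_up"`,
#'   `"none"`), `fisher_p`, `mww_p`, `auc`, `cv_accuracy`.
#' @export
discriminate <- function(pos, neg, scale = NA_character_, cv_folds = 10L,
                         seed = NULL) {
  stopifnot(length(pos) >= 1L, length(neg) >= 1L)
  thr <- median(c(pos, neg))
  a <- sum(pos > thr); b <- length(pos) - a
  c <- sum(neg > thr); d <- length(neg) - c
  degenerate <- length(unique(c(pos, neg))) == 1L
  p1 <- a / (a + b); p2 <- c / (c + d)
  direction <- if (degenerate || p1 == p2) "none"
               else if (p1 > p2) "positive_up" else "negative_up"
  cv <- if (is.null(seed)) .cv_accuracy(pos, neg, cv_folds)
        else withr::with_seed(seed, .cv_accuracy(pos, neg, cv_folds))
  tibble::tibble(
    scale = scale, n_pos = length(pos), n_neg = length(neg),
    threshold = thr, a = a, b = b, c = c, d = d,
    direction = direction,
    fisher_p = if (degenerate) 1 else fisher_exact_onesided(a, b, c, d),
    mww_p = if (degenerate) 1 else mww_test(pos, neg),
    auc = roc_auc(pos, neg),
    cv_accuracy = cv
  )
}

#' Discrimination analysis for every scale in a score table
#'
#' Splits a long score table (from [score_sequences()]) by scale and runs
#' [discriminate()] on the positive-group vs negative-group scores of each.
#'
#' @param scores Long score tibble with a `group` column containing both
#'   `"positive"` and `"negative"` rows.
#' @param cv_folds,seed Passed to [discriminate()]; per-scale seeds are
#'   derived deterministically from `seed`.
#' @return A tibble with one row per scale (columns as [discriminate()],
#'   plus `property`).
#' @export
discriminate_scales <- function(scores, cv_folds = 10L, seed = 1L) {
  stopifnot(all(c("group", "scale", "score") %in% names(scores)))
  if (!"property" %in% names(scores)) scores$property <- NA_character_
  sc <- unique(scores$scale)
  res <- purrr::imap_dfr(stats::setNames(sc, sc), function(s, nm) {
    sub <- scores[scores$scale == s, ]
    pos <- sub$score[sub$group == "positive"]
    neg <- sub$score[sub$group == "negative"]
    if (!length(pos) || !length(neg)) {
      stop("scale ", s, ": need scores from both groups", call. = FALSE)
    }
    d <- discriminate(pos, neg, scale = s, cv_folds = cv_folds,
                      seed = if (is.null(seed)) NULL
                             else seed + match(s, sc))
    d$property <- sub$property[1L]
    d
  })
  res[c("property", setdiff(names(res), "property"))]
}

#' Read a protein-abundance table
#'
#' Two-column TSV `id<TAB>abundance` (header optional), abundance in linear
#' units; `log_transform = TRUE` applies log10.
#'
#' @param path TSV path.
#' @param log_transform Apply log10 to the abundance column.
#' @return A tibble with columns `id`, `abundance`.
#' @export
read_abundance <- function(path, log_transform = FALSE) {
  if (!file.exists(path)) stop("abundance file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = c("id", "abundance"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) > 0L && is.na(suppressWarnings(as.numeric(raw$abundance[1L])))) {
    raw <- raw[-1L, , drop = FALSE]   # header row
  }
  out <- tibble::tibble(id = raw$id,
                        abundance = as.numeric(raw$abundance))
  if (anyNA(out$abundance)) {
    stop("non-numeric abundance value(s) in ", path, call. = FALSE)
  }
  if (log_transform) out$abundance <- log10(out$abundance)
  out
}

#' Join protein records with an abundance table
#'
#' Inner join on exact protein id. The match rate and unmatched ids are
#' attached as attributes `match_rate` and `unmatched` and reported via a
#' message; zero matches is an error.
#'
#' @param data Protein or score tibble with an `id` column.
#' @param abundance Abundance tibble from [read_abundance()] (or a path).
#' @return The joined tibble with an `abundance` column.
#' @export
abundance_join <- function(data, abundance) {
  if (is.character(abundance)) abundance <- read_abundance(abundance)
  stopifnot("id" %in% names(data),
            all(c("id", "abundance") %in% names(abundance)))
  ids <- unique(data$id)
  matched <- intersect(ids, abundance$id)
  if (length(matched) == 0L) {
    stop("no overlapping identifiers between dataset and abundance table",
         call. = FALSE)
  }
  out <- dplyr::inner_join(data, abundance, by = "id")
  attr(out, "match_rate") <- length(matched) / length(ids)
  attr(out, "unmatched") <- setdiff(ids, abundance$id)
  message(sprintf("abundance join: %d/%d ids matched (%.1f%%)",
                  length(matched), length(ids),
                  100 * length(matched) / length(ids)))
  out
}
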