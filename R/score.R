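# Per-sequence propensity scoring.
#
# A sequence's score under a scale is the mean of its per-residue value
# profile after centered moving-average smoothing (truncated at the ends).
# window = 1 is the plain mean; even windows use the centered odd span
# 2*floor(window/2)+1. Ambiguity codes (X/B/Z/U) are skipped before
# smoothing, so the profile runs over scorable residues only.

.half_window <- function(window) {
  stopifnot(is.numeric(window), length(window) == 1L, window >= 1)
  as.integer(window) %/% 2L
}

#' Propensity score of a single sequence
#'
#' Reference single-sequence implementation: builds the per-residue value
#' profile, applies centered moving-average smoothing with truncation at the
#' sequence ends, and returns the mean of the smoothed profile. With
#' `window = 1` this is the plain mean of the residue values. Ambiguity
#' codes are skipped.
#'
#' @param sequence A character string over the amino-acid alphabet.
#' @param values Named numeric vector: scale value for each of the 20
#'   standard amino acids (or a tidy one-scale tibble from
#'   [scale_registry()]).
#' @param window Smoothing window in residues (>= 1).
#' @return The sequence score, or `NA_real_` if no residue is scorable.
#' @examples
#' kd <- scale_registry("HYDROPHOBICITY")
#' kd <- kd[kd$scale == "KYTJ820101", ]
#' sequence_score("MKVLAW", kd, window = 1)
#' @export
sequence_score <- function(sequence, values, window = 1L) {
  if (is.data.frame(values)) {
    stopifnot(length(unique(values$scale)) == 1L)
    values <- stats::setNames(values$value, values$residue)
  }
  stopifnot(setequal(names(values), AMINO_ACIDS))
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  prof <- unname(values[chars])       # NA for ambiguity/unknown codes
  prof <- prof[!is.na(prof)]
  L <- length(prof)
  if (L == 0L) return(NA_real_)
  h <- .half_window(window)
  if (h == 0L) return(mean(prof))
  smoothed <- vapply(seq_len(L), function(i) {
    mean(prof[max(1L, i - h):min(L, i + h)])
  }, numeric(1))
  mean(smoothed)
}

# Position weights such that score = sum_j w_j * value(residue_j); depends
# only on the scorable length and the window, which lets a whole dataset be
# scored against every scale with one matrix product.
.position_weights <- function(L, h) {
  if (h == 0L) return(rep.int(1 / L, L))
  i <- seq_len(L)
  len <- pmin(L, i + h) - pmax(1L, i - h) + 1L
  cs <- c(0, cumsum(1 / len))
  (cs[pmin(L, i + h) + 1L] - cs[pmax(1L, i - h)]) / L
}

#' Score every protein in a table against a set of propensity scales
#'
#' Computes the smoothed-mean propensity score of every record under every
#' scale. Records with zero scorable residues are dropped with a warning;
#' a dataset in which every record is unscorable raises an error.
#'
#' @param data Protein tibble (columns `dataset`, `group`, `id`,
#'   `sequence`), e.g. from [read_fasta()].
#' @param scales Tidy scale tibble ([scale_registry()] format).
#' @param window Smoothing window in residues (default 7).
#' @return A long tibble: `dataset`, `group`, `id`, `property`, `scale`,
#'   `score` — one row per record x scale.
#' @export
score_sequences <- function(data, scales = scale_registry(), window = 7L) {
  stopifnot(nrow(data) >= 1L)
  if (!"group" %in% names(data)) data$group <- "positive"
  V <- .scale_matrix(scales)
  props <- .scale_properties(scales)
  h <- .half_window(window)

  seq_idx <- strsplit(toupper(data$sequence), "", fixed = TRUE)
  C <- matrix(0, nrow = nrow(data), ncol = 20L)
  scorable <- logical(nrow(data))
  for (r in seq_len(nrow(data))) {
    idx <- match(seq_idx[[r]], AMINO_ACIDS)
    idx <- idx[!is.na(idx)]
    L <- length(idx)
    if (L == 0L) next
    scorable[r] <- TRUE
    w <- .position_weights(L, h)
    acc <- rowsum(w, idx)
    C[r, as.integer(rownames(acc))] <- acc
  }
  if (any(!scorable)) {
    warning(sum(!scorable), " record(s) with no scorable residue dropped: ",
            paste(head(data$id[!scorable], 5L), collapse = ", "),
            call. = FALSE)
  }
  lost <- setdiff(unique(data$dataset), unique(data$dataset[scorable]))
  if (length(lost)) {
    stop("all records unscorable in dataset(s): ",
         paste(lost, collapse = ", "), call. = FALSE)
  }
  data <- data[scorable, , drop = FALSE]
  S <- C[scorable, , drop = FALSE] %*% V   # records x scales

  out <- tibble::tibble(
    dataset = rep(data$dataset, times = ncol(S)),
    group = rep(data$group, times = ncol(S)),
    id = rep(data$id, times = ncol(S)),
    scale = rep(colnames(S), each = nrow(S)),
    score = as.vector(S)
  )
  out$property <- unname(props[out$scale])
  out[c("dataset", "group", "id", "property", "scale", "score")]
}
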