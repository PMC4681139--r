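# Command-line entry points and static report writers. Each cmd_* function
# is a plain R function over the package API that writes TSV/JSON artifacts
# plus the serialized run configuration and a log file into an output
# directory; inst/bin/multiclever dispatches the shell subcommands
# (simulate, grid, boxplot, go) onto them. Reruns with identical inputs,
# config and seed reproduce byte-identical TSV/JSON artifacts.

.write_tsv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.list),
                                      ~ purrr::map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.run_log <- function(dir, lines) {
  writeLines(lines, file.path(dir, "log.txt"))
  invisible(lines)
}

#' Assemble a run configuration
#'
#' All thresholds and inputs of a run in one list; serialized verbatim into
#' every output directory so runs are self-describing and reproducible.
#'
#' @param ... Named configuration entries (paths, thresholds, seed).
#' @return A named list of class `clever_config`.
#' @export
run_config <- function(...) {
  structure(list(...), class = "clever_config")
}

.write_config <- function(config, dir) {
  .write_json(unclass(config), file.path(dir, "config.json"))
}

#' Quartile/whisker summary of score distributions per scale and group
#'
#' Tukey box-plot numbers (quartiles, whiskers at 1.5 IQR) plus the
#' discrimination statistics (two-sided MWW p and AUC) per scale.
#'
#' @param scores Long score tibble with `group`, `scale`, `score`.
#' @return A tibble: one row per scale x group with `q1`, `median`, `q3`,
#'   `whisker_low`, `whisker_high`, `n`, plus per-scale `mww_p` and `auc`.
#' @export
boxplot_summary <- function(scores) {
  qs <- scores |>
    dplyr::group_by(.data$property, .data$scale, .data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      q1 = quantile(.data$score, 0.25, names = FALSE),
      median = median(.data$score),
      q3 = quantile(.data$score, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      whisker_low = .data$q1 - 1.5 * (.data$q3 - .data$q1),
      whisker_high = .data$q3 + 1.5 * (.data$q3 - .data$q1)
    )
  st <- scores |>
    dplyr::group_by(.data$property, .data$scale) |>
    dplyr::summarise(
      mww_p = mww_test(.data$score[.data$group == "positive"],
                       .data$score[.data$group == "negative"]),
      auc = roc_auc(.data$score[.data$group == "positive"],
                    .data$score[.data$group == "negative"]),
      .groups = "drop"
    )
  dplyr::left_join(qs, st, by = c("property", "scale"))
}

#' Box plot of propensity score distributions
#'
#' @param scores Long score tibble (optionally pre-filtered to a few
#'   scales).
#' @param scales Optional character vector restricting the scales shown.
#' @return A ggplot object.
#' @export
plot_score_boxplot <- function(scores, scales = NULL) {
  if (!is.null(scales)) scores <- scores[scores$scale %in% scales, ]
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$scale, y = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' ROC curve plot for one scale
#'
#' @param pos,neg Numeric score vectors.
#' @param label Curve label (e.g. the scale name).
#' @return A ggplot object (step curve with the diagonal reference).
#' @export
plot_roc <- function(pos, neg, label = "scale") {
  pts <- roc_points(pos, neg)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s (AUC = %.3f)", label,
                                  roc_auc(pos, neg))) +
    ggplot2::theme_minimal()
}

#' Run the comparison grid from FASTA inputs and write its artifacts
#'
#' Reads the positive/negative FASTA files, runs [run_grid()] and writes
#' `grid.tsv`, `grid.json`, `per_scale.tsv`, `config.json` and `log.txt`
#' into `out_dir`.
#'
#' @param positive,negative Character vectors of FASTA paths.
#' @param out_dir Output directory (created if missing).
#' @param properties Property groups to screen (`"all"` or a subset).
#' @param p_cut,majority,max_overlap,window,cv_folds,seed See [run_grid()].
#' @return The `clever_grid`, invisibly.
#' @export
cmd_grid <- function(positive, negative, out_dir, properties = "all",
                     p_cut = 1e-5, majority = 6L, max_overlap = 0.2,
                     window = 7L, cv_folds = 10L, seed = 1L) {
  for (f in c(positive, negative)) {
    if (!file.exists(f)) stop("input FASTA not found: ", f, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- run_config(command = "grid", positive = positive,
                       negative = negative, properties = properties,
                       p_cut = p_cut, majority = majority,
                       max_overlap = max_overlap, window = window,
                       cv_folds = cv_folds, seed = seed)
  data <- read_datasets(positive, negative)
  grid <- run_grid(data, scales = scale_registry(properties),
                   p_cut = p_cut, majority = majority,
                   max_overlap = max_overlap, window = window,
                   cv_folds = cv_folds, seed = seed)
  .write_tsv(grid$cells, file.path(out_dir, "grid.tsv"))
  .write_tsv(grid$per_scale, file.path(out_dir, "per_scale.tsv"))
  .write_json(list(config = grid$config, cells = grid$cells),
              file.path(out_dir, "grid.json"))
  .write_config(config, out_dir)
  .run_log(out_dir, c(
    sprintf("datasets: %s", paste(unique(data$dataset), collapse = ", ")),
    sprintf("records: %d", nrow(data)),
    sprintf("cells: %d", nrow(grid$cells)),
    sprintf("states: %s",
            paste(names(table(grid$cells$state)), table(grid$cells$state),
                  sep = "=", collapse = " "))
  ))
  invisible(grid)
}

#' Box-plot summary of the best-performing scales and write its artifacts
#'
#' Scores the inputs, restricts to an explicit scale selection or to the
#' best scale per property (minimal Fisher p, the grid-to-Boxplotter
#' hand-off), and writes `boxplot_summary.tsv`, `roc_points.tsv`, the
#' config and log — plus `abundance_summary.tsv` when an abundance table
#' is supplied.
#'
#' @param positive,negative Character vectors of FASTA paths.
#' @param out_dir Output directory.
#' @param scales Character vector of scale names, or `NULL` to auto-select
#'   the best scale per property.
#' @param abundance Optional abundance TSV path.
#' @param log_abundance Log10-transform abundances on load.
#' @param window,cv_folds,seed See [run_grid()].
#' @return The summary tibble, invisibly.
#' @export
cmd_boxplot <- function(positive, negative, out_dir, scales = NULL,
                        abundance = NULL, log_abundance = FALSE,
                        window = 7L, cv_folds = 10L, seed = 1L) {
  for (f in c(positive, negative)) {
    if (!file.exists(f)) stop("input FASTA not found: ", f, call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- run_config(command = "boxplot", positive = positive,
                       negative = negative, scales = scales,
                       abundance = abundance, log_abundance = log_abundance,
                       window = window, cv_folds = cv_folds, seed = seed)
  data <- read_datasets(positive, negative)
  scores <- score_sequences(data, window = window)
  if (length(scales) == 0L) scales <- NULL   # empty selection = auto-select
  if (!is.null(scales)) {
    unknown <- setdiff(scales, unique(scores$scale))
    if (length(unknown)) {
      stop("unknown scale(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    scores <- scores[scores$scale %in% scales, ]
  } else {
    res <- discriminate_scales(scores, cv_folds = cv_folds, seed = seed)
    best <- res |>
      dplyr::group_by(.data$property) |>
      dplyr::slice_min(.data$fisher_p, n = 1L, with_ties = FALSE) |>
      dplyr::pull(.data$scale)
    scores <- scores[scores$scale %in% best, ]
  }
  summ <- boxplot_summary(scores)
  .write_tsv(summ, file.path(out_dir, "boxplot_summary.tsv"))
  roc <- scores |>
    dplyr::group_by(.data$scale) |>
    dplyr::group_modify(function(g, key) {
      roc_points(g$score[g$group == "positive"],
                 g$score[g$group == "negative"])
    }) |>
    dplyr::ungroup()
  .write_tsv(roc, file.path(out_dir, "roc_points.tsv"))
  log_lines <- sprintf("scales summarised: %s",
                       paste(unique(summ$scale), collapse = ", "))
  if (!is.null(abundance)) {
    ab <- read_abundance(abundance, log_transform = log_abundance)
    joined <- suppressMessages(abundance_join(data, ab))
    ab_summ <- joined |>
      dplyr::group_by(.data$dataset, .data$group) |>
      dplyr::summarise(
        n = dplyr::n(),
        q1 = quantile(.data$abundance, 0.25, names = FALSE),
        median = median(.data$abundance),
        q3 = quantile(.data$abundance, 0.75, names = FALSE),
        .groups = "drop"
      )
    pos_ab <- joined$abundance[joined$group == "positive"]
    neg_ab <- joined$abundance[joined$group == "negative"]
    ab_summ$mww_p <- mww_test(pos_ab, neg_ab)
    ab_summ$auc <- roc_auc(pos_ab, neg_ab)
    ab_summ$match_rate <- attr(joined, "match_rate")
    .write_tsv(ab_summ, file.path(out_dir, "abundance_summary.tsv"))
    log_lines <- c(log_lines, sprintf("abundance match rate: %.3f",
                                      attr(joined, "match_rate")))
  }
  .write_config(config, out_dir)
  .run_log(out_dir, log_lines)
  invisible(summ)
}

#' Run GO enrichment + clustering and write its artifacts
#'
#' Per namespace: enrichment table (`enrichment_<ns>.tsv`), cluster JSON
#' with nodes, similarity-weighted edges, membership and coverage lists
#' (`clusters_<ns>.json`), plus config and log.
#'
#' @param study Path to a text file of study protein ids (one per line),
#'   or a character vector of ids.
#' @param obo OBO ontology path.
#' @param annotations GAF path (detected by `.gaf` extension or `!`
#'   header) or two-column id-term TSV path.
#' @param out_dir Output directory.
#' @param p_cut Bonferroni p-value cutoff for the clustered terms.
#' @param sim_threshold Semantic-similarity threshold for clustering.
#' @param min_depth,min_precision,text Term filters ([filter_terms()]).
#' @param measure Similarity measure (`"lin"` or `"resnik"`).
#' @param exclude_iea Drop IEA annotations (GAF input only).
#' @param include_part_of Load `part_of` edges from the OBO file.
#' @return A list with the enrichment tibble and the `clever_clusters`,
#'   invisibly.
#' @export
cmd_go <- function(study, obo, annotations, out_dir, p_cut = 0.05,
                   sim_threshold = 0.5, min_depth = 0L, min_precision = 0,
                   text = NULL, measure = "lin", exclude_iea = FALSE,
                   include_part_of = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- run_config(command = "go",
                       study = if (length(study) == 1L && file.exists(study))
                         study else "inline",
                       obo = obo, annotations = annotations, p_cut = p_cut,
                       sim_threshold = sim_threshold, min_depth = min_depth,
                       min_precision = min_precision, text = text,
                       measure = measure, exclude_iea = exclude_iea,
                       include_part_of = include_part_of)
  if (length(study) == 1L && file.exists(study)) {
    study <- readLines(study, warn = FALSE)
    study <- study[nzchar(study)]
  }
  ontology <- read_obo(obo, include_part_of = include_part_of)
  mapping <- if (grepl("\\.gaf(\\.|$)", annotations) ||
                 startsWith(readLines(annotations, n = 1L), "!")) {
    read_gaf(annotations, exclude_iea = exclude_iea)
  } else {
    read_term_mapping(annotations)
  }
  ann <- build_annotations(mapping[c("id", "term")], ontology)
  enr <- enrich_terms(ann, study, ontology)
  log_lines <- sprintf("study: %d ids; population: %d; terms tested: %d",
                       length(attr(enr, "study")), length(ann$population),
                       nrow(enr))
  for (ns in unique(enr$namespace)) {
    sub <- enr[enr$namespace == ns, ]
    attr(sub, "study") <- attr(enr, "study")
    .write_tsv(sub, file.path(out_dir, paste0("enrichment_", ns, ".tsv")))
    kept <- filter_terms(sub, min_depth = min_depth,
                         min_precision = min_precision, p_cut = p_cut,
                         text = text)
    if (nrow(kept) == 0L) {
      log_lines <- c(log_lines,
                     sprintf("%s: no terms pass the filters", ns))
      next
    }
    cl <- cluster_terms(kept, ontology, ann, sim_threshold = sim_threshold,
                        measure = measure)
    .write_json(list(
      namespace = ns, sim_threshold = sim_threshold, measure = measure,
      nodes = kept[c("term", "name", "p_bonferroni", "depth", "precision",
                     "coverage")],
      edges = if (nrow(cl$edges)) cl$edges[c("from", "to", "similarity")]
              else list(),
      clusters = dplyr::select(cl$clusters, -"covered"),
      coverage = stats::setNames(cl$clusters$covered, cl$clusters$cluster)
    ), file.path(out_dir, paste0("clusters_", ns, ".json")))
    log_lines <- c(log_lines,
                   sprintf("%s: %d terms kept, %d cluster(s)", ns,
                           nrow(kept), nrow(cl$clusters)))
  }
  .write_config(config, out_dir)
  .run_log(out_dir, log_lines)
  invisible(list(enrichment = enr))
}

#' Generate synthetic fixtures and write them to disk
#'
#' Writes a biased positive set, a null negative set, a toy ontology
#' (OBO + GAF), a study id list and an abundance table under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param n Sequences per set.
#' @param scale Target scale name for the positive-set bias.
#' @param effect Tilt strength.
#' @param seed Integer seed.
#' @return Named list of the written paths, invisibly.
#' @export
cmd_simulate <- function(out_dir, n = 100L, scale = "KYTJ820101",
                         effect = 2, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- run_config(command = "simulate", n = n, scale = scale,
                       effect = effect, seed = seed)
  pos <- make_biased_dataset(n = n, scale = scale, effect = effect,
                             seed = seed, dataset = "biased",
                             group = "positive")
  neg <- make_biased_dataset(n = n, effect = 0, seed = seed + 1L,
                             dataset = "background", group = "negative")
  toy <- make_toy_ontology(n_branches = 3L, depth = 2L, pop = 2L * n,
                           seed = seed + 2L)
  paths <- list(
    positive = file.path(out_dir, "positive.fasta"),
    negative = file.path(out_dir, "negative.fasta"),
    obo = file.path(out_dir, "toy.obo"),
    gaf = file.path(out_dir, "toy.gaf"),
    study = file.path(out_dir, "study_ids.txt"),
    abundance = file.path(out_dir, "abundance.tsv")
  )
  write_fasta(pos, paths$positive)
  write_fasta(neg, paths$negative)
  write_obo(toy$ontology, paths$obo)
  write_gaf(toy$mapping, paths$gaf)
  branch1 <- toy$ontology$terms$term[toy$ontology$terms$depth == 1L][1L]
  in_branch <- toy$annotations$propagated
  writeLines(sort(unique(in_branch$id[in_branch$term == branch1])),
             paths$study)
  ab <- make_abundance_table(dplyr::bind_rows(pos, neg), seed = seed + 3L)
  readr::write_tsv(ab, paths$abundance, progress = FALSE)
  .write_config(config, out_dir)
  .run_log(out_dir, sprintf("wrote %s", unlist(paths)))
  invisible(paths)
}
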