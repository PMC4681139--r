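# Synthetic test-data generators: protein datasets with a controlled
# compositional tilt toward a chosen propensity scale, toy ontologies with
# balanced annotations, and abundance tables. Everything is seeded and
# reproducible, so the full pipeline is testable offline.

#' Generate a protein dataset with controlled compositional bias
#'
#' Sequences are drawn residue-by-residue i.i.d. from the composition
#' `p ~ background * exp(effect * z)`, where `z` is the standardised
#' (mean 0, sd 1 across the 20 residues) value vector of the target scale
#' — an exponential tilt with a single scalar effect size. `effect = 0`
#' reproduces the background composition exactly (uniform by default).
#' Sequence lengths are uniform over `length_range`.
#'
#' @param n Number of sequences.
#' @param length_range Length range `c(min, max)` in residues.
#' @param scale Target scale: a registry scale name, a tidy one-scale
#'   tibble, or a named 20-value vector. May be `NULL` when `effect = 0`.
#' @param effect Tilt strength (>= 0 toward high scale values; 0 = null).
#' @param background Background composition over the 20 standard amino
#'   acids (default
#'   uniform); any positive vector, normalised internally.
#' @param seed Integer seed (`NULL` = current RNG state).
#' @param dataset,group Labels for the output table.
#' @return A protein tibble as from [read_fasta()].
#' @examples
#' make_biased_dataset(n = 3, scale = "KYTJ820101", effect = 2, seed = 1)
#' @export
make_biased_dataset <- function(n = 100L, length_range = c(50L, 150L),
                                scale = NULL, effect = 0,
                                background = NULL, seed = NULL,
                                dataset = "synthetic", group = "positive") {
  stopifnot(n >= 1L, effect >= 0, length(length_range) == 2L,
            length_range[1L] >= 1L, length_range[1L] <= length_range[2L])
  if (is.null(background)) background <- rep(1 / 20, 20L)
  stopifnot(length(background) == 20L, all(background > 0))
  p <- background / sum(background)
  if (effect > 0) {
    if (is.null(scale)) stop("a target scale is required when effect > 0",
                             call. = FALSE)
    v <- .resolve_scale_values(scale)
    z <- (v - mean(v)) / sd(v)
    p <- p * exp(effect * z)
    p <- p / sum(p)
  }
  gen <- function() {
    lens <- sample(seq.int(length_range[1L], length_range[2L]), n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    tibble::tibble(dataset = dataset, group = group,
                   id = sprintf("%s_%05d", dataset, seq_len(n)),
                   sequence = seqs, length = lens)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

.resolve_scale_values <- function(scale) {
  if (is.character(scale) && length(scale) == 1L) {
    reg <- scale_registry()
    sub <- reg[reg$scale == scale, ]
    if (nrow(sub) == 0L) stop("unknown scale name: ", scale, call. = FALSE)
    return(stats::setNames(sub$value, sub$residue)[AMINO_ACIDS])
  }
  if (is.data.frame(scale)) {
    return(stats::setNames(scale$value, scale$residue)[AMINO_ACIDS])
  }
  stopifnot(is.numeric(scale), setequal(names(scale), AMINO_ACIDS))
  scale[AMINO_ACIDS]
}

#' Generate a toy ontology with balanced annotations
#'
#' Builds one namespace as a balanced tree: a root plus `n_branches^l`
#' terms at each level `l = 1..depth` (so `n_branches = 2, depth = 2`
#' yields 7 terms). Proteins `P0001...` are annotated round-robin to the
#' leaves — leaf counts are controlled exactly — after a seeded shuffle of
#' the protein order, so enriched study sets can be built by taking the
#' proteins of one branch.
#'
#' @param n_branches Branching factor (>= 2).
#' @param depth Tree depth below the root (>= 1).
#' @param pop Population size (number of annotated proteins).
#' @param seed Integer seed for the protein shuffle.
#' @param namespace Namespace label for all terms.
#' @return A list: `ontology` (`clever_ontology`), `annotations`
#'   (`clever_annotations`), `mapping` (direct id-term tibble) and
#'   `proteins` (population ids).
#' @export
make_toy_ontology <- function(n_branches = 2L, depth = 2L, pop = 16L,
                              seed = 1L, namespace = "molecular_function") {
  stopifnot(n_branches >= 2L, depth >= 1L, pop >= 1L)
  terms <- list(tibble::tibble(term = "TOY:0000000",
                               name = "toy root", namespace = namespace))
  edges <- list()
  prev <- "TOY:0000000"
  counter <- 0L
  for (l in seq_len(depth)) {
    n_l <- n_branches^l
    ids <- sprintf("TOY:%07d", counter + seq_len(n_l))
    counter <- counter + n_l
    parent_of <- rep(prev, each = n_branches)
    parent_no <- sub("^TOY:0*", "", parent_of)
    parent_no[parent_no == ""] <- "0"
    terms[[l + 1L]] <- tibble::tibble(
      term = ids,
      name = sprintf("branch %s level %d node %d", parent_no, l,
                     seq_len(n_l)),
      namespace = namespace)
    edges[[l]] <- tibble::tibble(child = ids, parent = parent_of)
    prev <- ids
  }
  ontology <- ontology_from_tables(dplyr::bind_rows(terms),
                                   dplyr::bind_rows(edges))
  leaves <- prev
  proteins <- sprintf("P%04d", seq_len(pop))
  shuffled <- withr::with_seed(seed, sample(proteins))
  mapping <- tibble::tibble(id = shuffled,
                            term = rep_len(leaves, pop))
  annotations <- build_annotations(mapping, ontology)
  list(ontology = ontology, annotations = annotations,
       mapping = mapping, proteins = proteins)
}

#' Generate a synthetic protein-abundance table
#'
#' Log-normal abundances, optionally correlated with a per-protein score
#' vector (negative `rho` emulates the anti-correlation between aggregation
#' propensity and expression level).
#'
#' @param data Protein tibble (source of ids).
#' @param meanlog,sdlog Log-normal parameters.
#' @param rho Correlation between `log(abundance)` and `signal` (requires
#'   `signal`).
#' @param signal Optional numeric vector (one value per protein) to
#'   correlate with.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `abundance`.
#' @export
make_abundance_table <- function(data, meanlog = 2, sdlog = 1, rho = 0,
                                 signal = NULL, seed = 1L) {
  ids <- unique(data$id)
  n <- length(ids)
  gen <- function() {
    eps <- stats::rnorm(n)
    lg <- if (!is.null(signal) && rho != 0) {
      z <- (signal - mean(signal)) / sd(signal)
      rho * z + sqrt(1 - rho^2) * eps
    } else eps
    tibble::tibble(id = ids, abundance = exp(meanlog + sdlog * lg))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Write an ontology to OBO format
#'
#' @param ontology A `clever_ontology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(ontology$edges$parent, ontology$edges$child)
  for (i in seq_len(nrow(ontology$terms))) {
    t <- ontology$terms[i, ]
    writeLines(c("[Term]",
                 paste0("id: ", t$term),
                 paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace),
                 paste0("is_a: ", by_child[[t$term]]),
                 ""), con)
  }
  invisible(path)
}

#' Write direct annotations to GAF 2.2 format
#'
#' @param mapping Direct annotation tibble (`id`, `term`).
#' @param path Output path.
#' @param db Database label for column 1.
#' @param aspect Aspect code for column 9.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(mapping, path, db = "TOY", aspect = "F") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  lines <- paste(db, mapping$id, mapping$id, "", mapping$term, "TOY:ref",
                 "IDA", "", aspect, "", "", "protein", "taxon:0000", "20200101",
                 db, "", "", sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
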