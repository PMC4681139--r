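#' Read a protein dataset from a FASTA file
#'
#' Parses a (wrapped or unwrapped) multi-record protein FASTA file into a
#' tidy protein table. Record ids are the header token up to the first
#' whitespace; sequences are upper-cased. Records whose sequence contains a
#' character outside the 20-letter amino-acid alphabet plus the ambiguity
#' codes `X/B/Z/U` are rejected with a warning; duplicate ids keep the first
#' occurrence.
#'
#' @param path Path to a FASTA file.
#' @param dataset Dataset name; defaults to the file name without extension.
#' @param group Group label for binary comparison, `"positive"` or
#'   `"negative"`.
#' @return A tibble with columns `dataset`, `group`, `id`, `sequence`,
#'   `length` (one row per protein record).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 desc", "MKV", ">p2", "AAAW"), fa)
#' read_fasta(fa, dataset = "demo")
#' @export
read_fasta <- function(path, dataset = NULL, group = c("positive", "negative")) {
  group <- match.arg(group)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (is.null(dataset)) {
    dataset <- sub("\\.[^.]*$", "", basename(path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("cannot parse FASTA file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("empty dataset: ", path, call. = FALSE)
  }
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- unname(toupper(as.character(set)))
  tbl <- tibble::tibble(dataset = dataset, group = group,
                        id = ids, sequence = seqs,
                        length = nchar(seqs))
  validate_proteins(tbl, context = path)
}

#' Validate a protein table
#'
#' Enforces the protein-record invariants: non-empty ids, sequences over the
#' amino-acid alphabet plus ambiguity codes, length >= 1, and unique ids
#' within each dataset (first occurrence kept). Invalid records are dropped
#' with a warning; an error is raised only if nothing survives.
#'
#' @param data A tibble with at least `dataset`, `id`, `sequence` columns.
#' @param context Label used in messages (e.g. the source file).
#' @return The validated tibble (possibly with rows dropped).
#' @export
validate_proteins <- function(data, context = "protein table") {
  stopifnot(all(c("dataset", "id", "sequence") %in% names(data)))
  data <- dplyr::mutate(data,
    sequence = toupper(.data$sequence),
    length = nchar(.data$sequence)
  )
  alphabet <- c(AMINO_ACIDS, AMBIGUITY_CODES)
  ok_alpha <- !stringr::str_detect(
    data$sequence, paste0("[^", paste(alphabet, collapse = ""), "]")
  )
  ok <- ok_alpha & data$length >= 1L & !is.na(data$id) & nzchar(data$id)
  if (any(!ok)) {
    warning(sum(!ok), " record(s) rejected in ", context,
            " (illegal residue characters or empty id/sequence): ",
            paste(head(data$id[!ok], 5L), collapse = ", "),
            call. = FALSE)
    data <- data[ok, , drop = FALSE]
  }
  dup <- duplicated(data[c("dataset", "id")])
  if (any(dup)) {
    warning(sum(dup), " duplicate id(s) dropped in ", context,
            " (first occurrence kept): ",
            paste(unique(head(data$id[dup], 5L)), collapse = ", "),
            call. = FALSE)
    data <- data[!dup, , drop = FALSE]
  }
  if (nrow(data) == 0L) {
    stop("no valid records in ", context, call. = FALSE)
  }
  data
}

#' Read several FASTA files into one positive/negative protein table
#'
#' @param positive,negative Character vectors of FASTA paths.
#' @return A combined protein tibble (one dataset per file).
#' @export
read_datasets <- function(positive = character(), negative = character()) {
  if (length(positive) + length(negative) == 0L) {
    stop("no input FASTA files given", call. = FALSE)
  }
  pos <- purrr::map(positive, read_fasta, group = "positive")
  neg <- purrr::map(negative, read_fasta, group = "negative")
  dplyr::bind_rows(pos, neg)
}

#' Write a protein table to FASTA
#'
#' @param data A protein tibble (columns `id`, `sequence`).
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, width = 60L) {
  set <- Biostrings::BStringSet(data$sequence)
  names(set) <- data$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Sequence overlap between two datasets
#'
#' Measures how strongly two datasets share material, on exact full-sequence
#' identity (not ids): the Jaccard index |intersection| / |union| of the two
#' sets of unique sequence strings. Shared ids are reported alongside. The
#' result is symmetric in the pair. Strongly overlapping pairs make the
#' enrichment statistics non-independent and are flagged "not calculable" in
#' the comparison grid.
#'
#' @param a,b Protein tibbles (as from [read_fasta()]), each one dataset.
#' @return A one-row tibble: `dataset_a`, `dataset_b`, `shared_ids`,
#'   `shared_sequences`, `jaccard`.
#' @export
compute_overlap <- function(a, b) {
  stopifnot(nrow(a) >= 1L, nrow(b) >= 1L)
  sa <- unique(a$sequence); sb <- unique(b$sequence)
  inter <- length(intersect(sa, sb))
  uni <- length(union(sa, sb))
  tibble::tibble(
    dataset_a = a$dataset[1L],
    dataset_b = b$dataset[1L],
    shared_ids = length(intersect(unique(a$id), unique(b$id))),
    shared_sequences = inter,
    jaccard = inter / uni
  )
}

#' Pairwise overlap report for all datasets in a protein table
#'
#' @param data A combined protein tibble holding >= 2 datasets.
#' @return A tibble with one row per unordered dataset pair (columns as
#'   [compute_overlap()]).
#' @export
overlap_report <- function(data) {
  ds <- unique(data$dataset)
  if (length(ds) < 2L) stop("need at least two datasets", call. = FALSE)
  pairs <- utils::combn(ds, 2L, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    compute_overlap(data[data$dataset == p[1L], ],
                    data[data$dataset == p[2L], ])
  })
}
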