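# Built-in propensity-scale registry.
#
# Five property groups are literature amino-acid indices drawn from the
# AAindex collection shipped with seqinr, selected and co-oriented so that
# within a group a higher value always means "more of the named property"
# (sign = -1 flips indices whose source measures the opposite direction).
# AGGREGATION and NUCLEIC_ACID_BINDING have no counterpart in AAindex; those
# two groups are documented composite scales built from AAindex ingredients
# (see .composite_scales below).

BUILTIN_PROPERTIES <- c("NUCLEIC_ACID_BINDING", "MEMBRANE", "ALPHA_HELIX",
                        "AGGREGATION", "BETA_SHEET", "BURIAL",
                        "HYDROPHOBICITY")

.builtin_accessions <- list(
  HYDROPHOBICITY = c(KYTJ820101 = 1, JURD980101 = 1, MANP780101 = 1,
                     EISD840101 = 1, PONP800101 = 1, WOLR790101 = 1,
                     FAUJ830101 = 1, BLAS910101 = 1, CASG920101 = 1,
                     ZIMJ680101 = 1),
  ALPHA_HELIX    = c(CHOP780201 = 1, BURA740101 = 1, CRAJ730101 = 1,
                     GEIM800101 = 1, ISOY800101 = 1, KANM800101 = 1,
                     LEVM780101 = 1, MAXF760101 = 1, NAGK730101 = 1,
                     PALJ810102 = 1),
  BETA_SHEET     = c(CHOP780202 = 1, PALJ810104 = 1, LIFS790101 = 1,
                     KANM800102 = 1, LEVM780102 = 1, GEIM800105 = 1,
                     ROBB760105 = 1, CRAJ730102 = 1, ISOY800102 = 1,
                     MAXF760102 = 1),
  BURIAL         = c(CHOC760104 = 1, CHOC760103 = 1, JANJ780102 = 1,
                     JANJ790101 = 1, NADH010102 = 1, NADH010101 = 1,
                     RADA880107 = 1, BIOV880101 = 1, FUKS010106 = 1,
                     WERD780101 = 1),
  MEMBRANE       = c(DESM900102 = 1, DESM900101 = 1, NAKH900110 = 1,
                     NAKH900111 = 1, NAKH900112 = 1, NAKH900109 = 1,
                     ARGP820103 = 1, CEDJ970103 = 1, PUNT030101 = -1,
                     PUNT030102 = -1)
)

.registry_env <- new.env(parent = emptyenv())

.aaindex_values <- function(aaindex, accession) {
  entry <- aaindex[[accession]]
  if (is.null(entry)) stop("unknown AAindex accession: ", accession)
  v <- unname(entry$I)          # aaindex order == AMINO_ACIDS order
  names(v) <- AMINO_ACIDS
  v
}

.zscore <- function(v) (v - mean(v)) / sd(v)

# Composite scales for the two property groups AAindex does not cover.
# Aggregation propensity follows the standard sequence-based rationale
# (hydrophobic + beta-prone + uncharged residues aggregate); nucleic-acid
# binding follows the charge/hydropathy profile of RNA/DNA-binding residues
# (basic, hydrophilic). Each group pairs a fixed charge ingredient with the
# ten hydrophobicity (and beta-sheet) indices so members are distinct but
# probe the same property.
.composite_scales <- function(aaindex) {
  hyd_acc <- names(.builtin_accessions$HYDROPHOBICITY)
  bet_acc <- names(.builtin_accessions$BETA_SHEET)
  pos_chg <- .aaindex_values(aaindex, "FAUJ880111")
  neg_chg <- .aaindex_values(aaindex, "FAUJ880112")
  net_chg <- .aaindex_values(aaindex, "KLEP840101")
  chg_mag <- pos_chg + neg_chg
  out <- list()
  for (i in seq_along(hyd_acc)) {
    h <- .aaindex_values(aaindex, hyd_acc[i])
    b <- .aaindex_values(aaindex, bet_acc[i])
    out[[sprintf("AGG%02d", i)]] <- list(
      property = "AGGREGATION",
      values = .zscore(h) + .zscore(b) - .zscore(chg_mag),
      provenance = sprintf(
        "composite: z(%s) + z(%s) - z(charge magnitude, FAUJ880111+FAUJ880112)",
        hyd_acc[i], bet_acc[i])
    )
    out[[sprintf("NAB%02d", i)]] <- list(
      property = "NUCLEIC_ACID_BINDING",
      values = .zscore(pos_chg) + .zscore(net_chg) - .zscore(h),
      provenance = sprintf(
        "composite: z(positive charge, FAUJ880111) + z(net charge, KLEP840101) - z(%s)",
        hyd_acc[i])
    )
  }
  out
}

.build_registry <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  aaindex <- get("aaindex", envir = env)
  rows <- list()
  for (prop in names(.builtin_accessions)) {
    signs <- .builtin_accessions[[prop]]
    for (acc in names(signs)) {
      v <- .aaindex_values(aaindex, acc) * signs[[acc]]
      prov <- paste0("AAindex ", acc, ": ", aaindex[[acc]]$D,
                     if (signs[[acc]] < 0) " [sign-flipped]" else "")
      rows[[acc]] <- tibble::tibble(
        scale = acc, property = prop, residue = AMINO_ACIDS,
        value = unname(v), provenance = prov
      )
    }
  }
  for (nm in names(comp <- .composite_scales(aaindex))) {
    rows[[nm]] <- tibble::tibble(
      scale = nm, property = comp[[nm]]$property, residue = AMINO_ACIDS,
      value = unname(comp[[nm]]$values), provenance = comp[[nm]]$provenance
    )
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(!anyNA(out$value), all(is.finite(out$value)))
  out
}

#' Built-in propensity-scale registry
#'
#' Returns the registry of amino-acid propensity scales in long (tidy) form:
#' one row per scale x residue. Seven built-in property groups of ten scales
#' each: `NUCLEIC_ACID_BINDING`, `MEMBRANE`, `ALPHA_HELIX`, `AGGREGATION`,
#' `BETA_SHEET`, `BURIAL`, `HYDROPHOBICITY`. Scales are used raw (no
#' normalisation); each is oriented so that higher values mean more of the
#' named property, and the `provenance` column records the source index (or
#' the composite formula) for every scale.
#'
#' @param properties Character vector of property-group names, or `"all"`.
#' @return A tibble with columns `scale`, `property`, `residue`, `value`,
#'   `provenance` (20 rows per scale).
#' @examples
#' dplyr::count(scale_registry(), property)
#' @export
scale_registry <- function(properties = "all") {
  if (is.null(.registry_env$registry)) {
    .registry_env$registry <- .build_registry()
  }
  reg <- .registry_env$registry
  if (!identical(properties, "all")) {
    unknown <- setdiff(properties, unique(reg$property))
    if (length(unknown)) {
      stop("unknown property group(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    reg <- reg[reg$property %in% properties, , drop = FALSE]
  }
  reg
}

#' Load a custom propensity scale from a two-column TSV file
#'
#' The file must contain exactly one row per standard amino acid:
#' `residue<TAB>value`, one-letter residue codes, numeric finite values.
#' A header line is tolerated. Errors name the offending row.
#'
#' @param path Path to the TSV file.
#' @param name Scale name; defaults to the file name without extension.
#' @param property Property-group label for the scale (custom groups may
#'   hold any number of scales).
#' @return A 20-row tidy scale tibble compatible with [scale_registry()]
#'   output.
#' @export
load_custom_scale <- function(path, name = NULL, property = "CUSTOM") {
  if (!file.exists(path)) stop("scale file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path, col_names = c("residue", "value"),
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  # tolerate a header row
  if (nrow(raw) > 0L && !(toupper(raw$residue[1L]) %in% AMINO_ACIDS)) {
    raw <- raw[-1L, , drop = FALSE]
  }
  raw$residue <- toupper(raw$residue)
  bad <- which(!(raw$residue %in% AMINO_ACIDS))
  if (length(bad)) {
    stop("unknown residue '", raw$residue[bad[1L]], "' in row ", bad[1L],
         " of ", path, call. = FALSE)
  }
  dup <- which(duplicated(raw$residue))
  if (length(dup)) {
    stop("duplicate residue '", raw$residue[dup[1L]], "' in row ", dup[1L],
         " of ", path, call. = FALSE)
  }
  missing <- setdiff(AMINO_ACIDS, raw$residue)
  if (length(missing)) {
    stop("missing residue(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(vals) | !is.finite(vals))
  if (length(bad)) {
    stop("non-numeric or non-finite value '", raw$value[bad[1L]],
         "' for residue ", raw$residue[bad[1L]], " in ", path, call. = FALSE)
  }
  ord <- match(AMINO_ACIDS, raw$residue)
  tibble::tibble(scale = name, property = property,
                 residue = AMINO_ACIDS, value = vals[ord],
                 provenance = paste0("custom scale loaded from ", basename(path)))
}

#' Build a tidy scale tibble from a named value vector
#'
#' Convenience constructor used for ad-hoc and synthetic scales.
#'
#' @param values Named numeric vector with one value for each of the 20
#'   standard amino acids.
#' @param name Scale name.
#' @param property Property-group label.
#' @return A 20-row tidy scale tibble.
#' @export
as_scale <- function(values, name = "custom", property = "CUSTOM") {
  stopifnot(is.numeric(values), length(values) == 20L,
            setequal(names(values), AMINO_ACIDS), all(is.finite(values)))
  tibble::tibble(scale = name, property = property, residue = AMINO_ACIDS,
                 value = unname(values[AMINO_ACIDS]),
                 provenance = "in-memory scale")
}

# 20 x n_scales value matrix from a tidy scale tibble (internal).
.scale_matrix <- function(scales) {
  wide <- tidyr::pivot_wider(scales[c("scale", "residue", "value")],
                             names_from = "scale", values_from = "value")
  m <- as.matrix(wide[match(AMINO_ACIDS, wide$residue), -1, drop = FALSE])
  rownames(m) <- AMINO_ACIDS
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("scale table is incomplete (missing residue values)",
                     call. = FALSE)
  m
}

# scale -> property lookup (internal).
.scale_properties <- function(scales) {
  u <- dplyr::distinct(scales, .data$scale, .data$property)
  stats::setNames(u$property, u$scale)
}
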