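# Gene Ontology toolkit: OBO/GAF ingestion, true-path annotation
# propagation, hypergeometric term enrichment with Bonferroni correction,
# information content, Lin/Resnik semantic similarity, and
# similarity-threshold clustering with protein coverage.

#' Build an ontology object from term and edge tables
#'
#' Validates the DAG invariants (acyclicity, known endpoints), determines
#' the namespace roots (parentless terms), and precomputes term depth
#' (longest path from the root), level (shortest path) and ancestor
#' closures.
#'
#' @param terms Tibble with columns `term`, `name`, `namespace`.
#' @param edges Tibble with columns `child`, `parent` (and optionally
#'   `relation`).
#' @return A `clever_ontology` object.
#' @export
ontology_from_tables <- function(terms, edges) {
  stopifnot(all(c("term", "name", "namespace") %in% names(terms)))
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges <- edges[edges$child %in% terms$term & edges$parent %in% terms$term, ]
  g <- igraph::graph_from_data_frame(
    edges[c("child", "parent")], directed = TRUE,
    vertices = terms$term
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1L]][1L]
    stop("cycle detected in ontology involving term ", bad, call. = FALSE)
  }
  n <- nrow(terms)
  idx <- stats::setNames(seq_len(n), terms$term)
  parents <- split(idx[edges$parent], edges$child)   # child id -> parent idx
  topo <- names(igraph::topo_sort(g, mode = "out"))  # parents before children? no:
  # edges run child -> parent, so "out" order lists children before their
  # parents; reverse it to process parents first.
  topo <- rev(topo)
  depth <- level <- stats::setNames(rep(0L, n), terms$term)
  anc <- stats::setNames(vector("list", n), terms$term)
  for (t in topo) {
    p <- parents[[t]]
    if (is.null(p) || length(p) == 0L) {
      anc[[t]] <- t
    } else {
      pn <- terms$term[p]
      depth[t] <- max(depth[pn]) + 1L
      level[t] <- min(level[pn]) + 1L
      anc[[t]] <- unique(c(t, unlist(anc[pn], use.names = FALSE)))
    }
  }
  terms$depth <- unname(depth[terms$term])
  terms$level <- unname(level[terms$term])
  roots <- terms$term[!(terms$term %in% edges$child)]
  root_ns <- terms$namespace[match(roots, terms$term)]
  structure(
    list(terms = tibble::as_tibble(terms), edges = tibble::as_tibble(edges),
         roots = stats::setNames(roots, root_ns), ancestors = anc),
    class = "clever_ontology"
  )
}

#' @export
print.clever_ontology <- function(x, ...) {
  cat("<clever_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " edges, namespaces: ",
      paste(unique(x$terms$namespace), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read an OBO 1.2/1.4 ontology file
#'
#' Line-based stanza parser: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a` (and optionally `relationship: part_of`) fields.
#' Obsolete terms are skipped; cycles are rejected with an error naming a
#' cycle member.
#'
#' @param path OBO file path.
#' @param include_part_of Also load `relationship: part_of` edges.
#' @return A `clever_ontology` object (see [ontology_from_tables()]).
#' @export
read_obo <- function(path, include_part_of = FALSE) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stanza_at <- grepl("^\\[", lines)
  ids <- which(stanza_at & lines == "[Term]")
  if (length(ids) == 0L) stop("no [Term] stanzas in ", path, call. = FALSE)
  bounds <- c(which(stanza_at), length(lines) + 1L)
  terms <- list(); edges <- list()
  for (s in ids) {
    end <- bounds[match(s, bounds) + 1L] - 1L
    chunk <- lines[(s + 1L):end]
    get1 <- function(key) {
      v <- chunk[startsWith(chunk, paste0(key, ":"))]
      if (!length(v)) return(NA_character_)
      sub("\\s*!.*$", "", sub(paste0("^", key, ":\\s*"), "", v[1L]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    terms[[id]] <- tibble::tibble(
      term = id,
      name = ifelse(is.na(get1("name")), id, get1("name")),
      namespace = ifelse(is.na(get1("namespace")), "default", get1("namespace"))
    )
    isa <- chunk[startsWith(chunk, "is_a:")]
    parents <- sub("\\s*!.*$", "", sub("^is_a:\\s*", "", isa))
    rel <- character(0)
    if (include_part_of) {
      po <- chunk[grepl("^relationship:\\s*part_of\\s", chunk)]
      rel <- sub("\\s*!.*$", "",
                 sub("^relationship:\\s*part_of\\s+", "", po))
    }
    if (length(parents) + length(rel)) {
      edges[[id]] <- tibble::tibble(
        child = id, parent = c(parents, rel),
        relation = c(rep("is_a", length(parents)),
                     rep("part_of", length(rel)))
      )
    }
  }
  ontology_from_tables(dplyr::bind_rows(terms), dplyr::bind_rows(edges))
}

#' Read a GO annotation file (GAF 2.x)
#'
#' Comment lines (`!`) are skipped; columns 2 (object id), 5 (GO id) and 7
#' (evidence code) are used.
#'
#' @param path GAF file path.
#' @param exclude_iea Drop electronically inferred (`IEA`) annotations.
#' @return A tibble with columns `id`, `term`, `evidence`.
#' @export
read_gaf <- function(path, exclude_iea = FALSE) {
  if (!file.exists(path)) stop("GAF file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 7L) stop("not a GAF file (fewer than 7 columns): ", path,
                           call. = FALSE)
  out <- tibble::tibble(id = raw[[2L]], term = raw[[5L]],
                        evidence = raw[[7L]])
  if (exclude_iea) out <- out[out$evidence != "IEA", ]
  dplyr::distinct(out)
}

#' Read a two-column id-to-term annotation mapping
#'
#' @param path TSV path with columns `id<TAB>term` (header optional).
#' @return A tibble with columns `id`, `term`.
#' @export
read_term_mapping <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("id", "term"), col_types = "cc",
                         comment = "#", progress = FALSE)
  if (nrow(raw) > 0L && !grepl(":", raw$term[1L]) && raw$term[1L] == "term") {
    raw <- raw[-1L, , drop = FALSE]
  }
  dplyr::distinct(raw)
}

#' Propagate annotations over the ontology (true-path rule)
#'
#' Closes the direct annotations under the ancestor relation: a protein
#' annotated to a term is annotated to all its ancestors up to the
#' namespace root. Annotations to unknown terms are dropped with a warning.
#'
#' @param mapping Tibble with columns `id`, `term` (direct annotations).
#' @param ontology A `clever_ontology`.
#' @return A `clever_annotations` object: direct and propagated annotation
#'   tables, per-term propagated counts, and the population of annotated
#'   protein ids.
#' @export
build_annotations <- function(mapping, ontology) {
  stopifnot(all(c("id", "term") %in% names(mapping)))
  known <- mapping$term %in% ontology$terms$term
  if (any(!known)) {
    warning(sum(!known), " annotation(s) to unknown terms dropped",
            call. = FALSE)
    mapping <- mapping[known, , drop = FALSE]
  }
  if (nrow(mapping) == 0L) stop("no usable annotations", call. = FALSE)
  direct <- dplyr::distinct(mapping[c("id", "term")])
  anc_sizes <- lengths(ontology$ancestors[direct$term])
  propagated <- dplyr::distinct(tibble::tibble(
    id = rep(direct$id, anc_sizes),
    term = unlist(ontology$ancestors[direct$term], use.names = FALSE)
  ))
  counts <- dplyr::count(propagated, .data$term, name = "n_propagated")
  counts$namespace <- ontology$terms$namespace[
    match(counts$term, ontology$terms$term)]
  structure(
    list(direct = direct, propagated = propagated, counts = counts,
         population = unique(direct$id)),
    class = "clever_annotations"
  )
}

#' @export
print.clever_annotations <- function(x, ...) {
  cat("<clever_annotations> ", length(x$population), " proteins, ",
      nrow(x$direct), " direct / ", nrow(x$propagated),
      " propagated annotations\n", sep = "")
  invisible(x)
}

#' Term depth (longest is_a path from the namespace root)
#'
#' @param ontology A `clever_ontology`.
#' @param terms Character vector of term ids.
#' @return Integer vector of depths (root = 0).
#' @export
term_depth <- function(ontology, terms) {
  i <- match(terms, ontology$terms$term)
  if (anyNA(i)) {
    stop("unknown term(s): ", paste(terms[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(ontology$terms$depth[i], terms)
}

#' Information content of terms
#'
#' `IC(t) = -log(n_propagated(t) / n_propagated(root))` over the annotated
#' population, per namespace; the root (and any term annotated to the whole
#' namespace population) has IC 0. Terms with zero propagated annotations
#' have undefined IC and return `NA`.
#'
#' @param annotations A `clever_annotations`.
#' @param terms Character vector of term ids.
#' @return Named numeric vector of IC values (`NA` where undefined).
#' @export
information_content <- function(annotations, terms) {
  cnt <- annotations$counts
  root_n <- cnt |>
    dplyr::group_by(.data$namespace) |>
    dplyr::summarise(root_n = max(.data$n_propagated), .groups = "drop")
  i <- match(terms, cnt$term)
  n <- cnt$n_propagated[i]
  rn <- root_n$root_n[match(cnt$namespace[i], root_n$namespace)]
  stats::setNames(-log(n / rn), terms)
}

# IC of every term that has propagated annotations (internal).
.ic_table <- function(annotations) {
  cnt <- annotations$counts
  ic <- information_content(annotations, cnt$term)
  tibble::tibble(term = cnt$term, namespace = cnt$namespace, ic = unname(ic))
}

#' Semantic similarity between two terms
#'
#' Lin similarity `2 IC(MICA) / (IC(t1) + IC(t2))` where MICA is the common
#' ancestor with maximal information content; Resnik similarity (`IC(MICA)`,
#' unnormalised) is available behind `measure = "resnik"`. Two terms whose
#' only common ancestor is the root have similarity 0, as does any pair
#' with `IC(t1) + IC(t2) = 0`.
#'
#' @param ontology A `clever_ontology`.
#' @param annotations A `clever_annotations` (source of IC).
#' @param t1,t2 Term ids (same namespace, both with defined IC).
#' @param measure `"lin"` (default, in \[0, 1\]) or `"resnik"`.
#' @return Similarity value.
#' @export
lin_similarity <- function(ontology, annotations, t1, t2,
                           measure = c("lin", "resnik")) {
  measure <- match.arg(measure)
  ic <- information_content(annotations, unique(c(
    ontology$ancestors[[t1]], ontology$ancestors[[t2]])))
  common <- intersect(ontology$ancestors[[t1]], ontology$ancestors[[t2]])
  ic_common <- ic[common]
  ic_common <- ic_common[!is.na(ic_common)]
  mica <- if (length(ic_common)) max(ic_common) else 0
  if (measure == "resnik") return(mica)
  denom <- ic[[t1]] + ic[[t2]]
  if (is.na(denom) || denom == 0) return(0)
  min(1, 2 * mica / denom)
}

# Pairwise similarity matrix over a set of same-namespace terms (internal).
.similarity_matrix <- function(ontology, annotations, terms,
                               measure = "lin") {
  m <- length(terms)
  S <- matrix(0, m, m, dimnames = list(terms, terms))
  ic <- information_content(annotations, unique(unlist(
    ontology$ancestors[terms], use.names = FALSE)))
  for (i in seq_len(m)) {
    S[i, i] <- if (measure == "lin") {
      if (!is.na(ic[[terms[i]]]) && ic[[terms[i]]] > 0) 1 else 0
    } else {
      ic[[terms[i]]]
    }
    for (j in seq_len(i - 1L)) {
      common <- intersect(ontology$ancestors[[terms[i]]],
                          ontology$ancestors[[terms[j]]])
      icc <- ic[common]; icc <- icc[!is.na(icc)]
      mica <- if (length(icc)) max(icc) else 0
      s <- if (measure == "resnik") mica else {
        denom <- ic[[terms[i]]] + ic[[terms[j]]]
        if (is.na(denom) || denom == 0) 0 else min(1, 2 * mica / denom)
      }
      S[i, j] <- S[j, i] <- s
    }
  }
  S
}

#' GO term enrichment of a study set
#'
#' One-sided hypergeometric over-representation test of every term with at
#' least one propagated study annotation, against the annotated population.
#' Bonferroni correction is applied per namespace (family = terms tested in
#' that namespace). Reported alongside: term depth (longest root path),
#' level (shortest), precision (information content normalised by the
#' maximal IC among annotated terms of the namespace) and coverage
#' (`study_count / study_n`).
#'
#' @param annotations A `clever_annotations`.
#' @param study Character vector of study protein ids (must be drawn from
#'   the annotated population; ids outside it are dropped with a warning).
#' @param ontology A `clever_ontology`.
#' @return A tibble sorted by `p_raw`: `term`, `name`, `namespace`,
#'   `study_count`, `study_n`, `pop_count`, `pop_n`, `p_raw`,
#'   `p_bonferroni`, `depth`, `level`, `precision`, `coverage`. The study
#'   ids used are attached as attribute `"study"`.
#' @export
enrich_terms <- function(annotations, study, ontology) {
  study <- unique(study)
  if (length(study) == 0L) stop("empty study set", call. = FALSE)
  outside <- setdiff(study, annotations$population)
  if (length(outside)) {
    warning(length(outside), " study id(s) not in the annotated population",
            " were dropped: ", paste(head(outside, 5L), collapse = ", "),
            call. = FALSE)
    study <- intersect(study, annotations$population)
  }
  if (length(study) == 0L) {
    stop("no study ids found in the annotated population", call. = FALSE)
  }
  pop_n <- length(annotations$population)
  study_n <- length(study)
  prop <- annotations$propagated
  study_counts <- dplyr::count(prop[prop$id %in% study, ], .data$term,
                               name = "study_count")
  res <- dplyr::inner_join(study_counts, annotations$counts, by = "term")
  res$p_raw <- phyper(res$study_count - 1L, res$n_propagated,
                      pop_n - res$n_propagated, study_n, lower.tail = FALSE)
  res <- res |>
    dplyr::group_by(.data$namespace) |>
    dplyr::mutate(p_bonferroni = pmin(1, dplyr::n() * .data$p_raw)) |>
    dplyr::ungroup()
  ti <- match(res$term, ontology$terms$term)
  ic <- .ic_table(annotations)
  ic_max <- ic |>
    dplyr::group_by(.data$namespace) |>
    dplyr::summarise(ic_max = max(.data$ic), .groups = "drop")
  res_ic <- ic$ic[match(res$term, ic$term)]
  denom <- ic_max$ic_max[match(res$namespace, ic_max$namespace)]
  out <- tibble::tibble(
    term = res$term,
    name = ontology$terms$name[ti],
    namespace = res$namespace,
    study_count = res$study_count, study_n = study_n,
    pop_count = res$n_propagated, pop_n = pop_n,
    p_raw = res$p_raw, p_bonferroni = res$p_bonferroni,
    depth = ontology$terms$depth[ti], level = ontology$terms$level[ti],
    precision = ifelse(denom > 0, res_ic / denom, 0),
    coverage = res$study_count / study_n
  )
  out <- dplyr::arrange(out, .data$p_raw, .data$term)
  attr(out, "study") <- study
  out
}

#' Filter an enrichment table
#'
#' Conjunctive filter on term depth, precision, Bonferroni-corrected
#' p-value and a case-insensitive substring match on the term name.
#'
#' @param terms Enrichment tibble from [enrich_terms()].
#' @param min_depth Minimum term depth.
#' @param min_precision Minimum precision (normalised IC).
#' @param p_cut Maximum Bonferroni-corrected p-value.
#' @param text Substring the term name must contain (case-insensitive);
#'   `NULL` for no text filter.
#' @return The filtered tibble (study attribute preserved).
#' @export
filter_terms <- function(terms, min_depth = 0L, min_precision = 0,
                         p_cut = 1, text = NULL) {
  keep <- terms$depth >= min_depth & terms$precision >= min_precision &
    terms$p_bonferroni <= p_cut
  if (!is.null(text) && nzchar(text)) {
    keep <- keep & grepl(tolower(text), tolower(terms$name), fixed = TRUE)
  }
  out <- terms[keep, , drop = FALSE]
  attr(out, "study") <- attr(terms, "study")
  out
}

#' Cluster enriched terms by semantic similarity
#'
#' Builds, per namespace, a graph over the given terms with an edge wherever
#' the pairwise semantic similarity reaches `sim_threshold`; clusters are
#' the connected components (raising the threshold refines the clustering).
#' Each cluster reports its representative (lowest corrected p-value),
#' member terms, and coverage: the distinct study proteins annotated
#' (propagated) to at least one member term.
#'
#' @param terms Enrichment tibble from [enrich_terms()] (possibly
#'   filtered); its `"study"` attribute supplies the study ids unless
#'   `study` is given.
#' @param ontology A `clever_ontology`.
#' @param annotations A `clever_annotations`.
#' @param sim_threshold Similarity threshold in \[0, 1\] (default 0.5).
#' @param measure `"lin"` or `"resnik"` (see [lin_similarity()]).
#' @param study Optional character vector of study ids for coverage.
#' @return A `clever_clusters` object: `clusters` tibble (`namespace`,
#'   `cluster`, `n_terms`, `representative`, `representative_name`,
#'   `min_p`, `coverage_count`, list-columns `members` and `covered`),
#'   `edges` tibble with similarity weights, term-to-cluster `assignment`,
#'   and the threshold used.
#' @export
cluster_terms <- function(terms, ontology, annotations, sim_threshold = 0.5,
                          measure = c("lin", "resnik"), study = NULL) {
  measure <- match.arg(measure)
  if (is.null(study)) study <- attr(terms, "study")
  prop <- annotations$propagated
  if (!is.null(study)) prop <- prop[prop$id %in% study, ]
  clusters <- list(); edge_rows <- list(); assign_rows <- list()
  for (ns in unique(terms$namespace)) {
    tt <- dplyr::distinct(terms[terms$namespace == ns, ], .data$term,
                          .keep_all = TRUE)
    S <- .similarity_matrix(ontology, annotations, tt$term, measure)
    m <- nrow(tt)
    ij <- which(upper.tri(S) & S >= sim_threshold, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = tt$term[ij[, 1L]], to = tt$term[ij[, 2L]]),
      directed = FALSE, vertices = tt$term)
    comp <- igraph::components(g)
    memb <- comp$membership[tt$term]
    if (nrow(ij)) {
      edge_rows[[ns]] <- tibble::tibble(
        namespace = ns, from = tt$term[ij[, 1L]], to = tt$term[ij[, 2L]],
        similarity = S[ij])
    }
    for (k in sort(unique(memb))) {
      members <- tt$term[memb == k]
      sub <- tt[tt$term %in% members, ]
      rep_i <- order(sub$p_bonferroni, sub$p_raw, sub$term)[1L]
      covered <- unique(prop$id[prop$term %in% members])
      cid <- paste0(ns, ".", k)
      clusters[[cid]] <- tibble::tibble(
        namespace = ns, cluster = cid, n_terms = length(members),
        representative = sub$term[rep_i],
        representative_name = sub$name[rep_i],
        min_p = sub$p_bonferroni[rep_i],
        coverage_count = length(covered),
        members = list(members), covered = list(sort(covered))
      )
      assign_rows[[cid]] <- tibble::tibble(term = members, cluster = cid)
    }
  }
  structure(
    list(clusters = dplyr::bind_rows(clusters),
         edges = dplyr::bind_rows(edge_rows),
         assignment = dplyr::bind_rows(assign_rows),
         sim_threshold = sim_threshold, measure = measure),
    class = "clever_clusters"
  )
}

#' @export
print.clever_clusters <- function(x, ...) {
  cat("<clever_clusters> ", nrow(x$clusters), " cluster(s) at threshold ",
      x$sim_threshold, " (", x$measure, ")\n", sep = "")
  invisible(x)
}

#' @describeIn cluster_terms Tidy cluster table (list columns dropped).
#' @param x A `clever_clusters` object.
#' @param ... Unused.
#' @export
tidy.clever_clusters <- function(x, ...) {
  dplyr::select(x$clusters, -"members", -"covered")
}

#' @describeIn cluster_terms Similarity-graph plot of the clustered terms.
#' @param object A `clever_clusters` object.
#' @param seed Layout seed.
#' @export
autoplot.clever_clusters <- function(object, seed = 1L, ...) {
  nodes <- object$assignment
  g <- igraph::graph_from_data_frame(
    if (nrow(object$edges)) object$edges[c("from", "to")]
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nodes$term)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes$x <- xy[, 1L]; nodes$y <- xy[, 2L]
  ed <- object$edges
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(ed) && nrow(ed)) {
    ed$x <- nodes$x[match(ed$from, nodes$term)]
    ed$y <- nodes$y[match(ed$from, nodes$term)]
    ed$xend <- nodes$x[match(ed$to, nodes$term)]
    ed$yend <- nodes$y[match(ed$to, nodes$term)]
    p <- p + ggplot2::geom_segment(
      data = ed, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, alpha = .data$similarity),
      colour = "grey50")
  }
  p + ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "cluster", alpha = "similarity")
}
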