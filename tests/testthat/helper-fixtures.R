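# Shared fixtures, built in code.

# Synthetic scale registry: n_groups property groups with mutually
# orthogonal (and centred) base value vectors, plus small member noise
# within each group — so a compositional tilt toward one group leaves the
# others unbiased by construction. Used wherever a test must not depend on
# the literature scale values.
synth_registry <- function(n_groups = 7L, n_scales = 10L, seed = 42L,
                           member_noise = 0.15) {
  withr::with_seed(seed, {
    M <- cbind(1, matrix(stats::rnorm(20L * n_groups), 20L))
    Q <- qr.Q(qr(M))[, -1L, drop = FALSE]  # orthonormal, centred bases
    rows <- list()
    for (g in seq_len(n_groups)) {
      base <- sqrt(20) * Q[, g]            # unit variance across residues
      for (k in seq_len(n_scales)) {
        v <- base + member_noise * stats::rnorm(20L)
        names(v) <- multiclever:::AMINO_ACIDS
        rows[[paste0(g, "_", k)]] <- as_scale(
          v, name = sprintf("SG%02dS%02d", g, k),
          property = sprintf("PROP%02d", g))
      }
    }
    dplyr::bind_rows(rows)
  })
}

write_temp_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(purrr::imap(entries, function(s, id) c(paste0(">", id), s))),
             path)
  path
}

# Toy protein table from raw sequences.
protein_table <- function(seqs, dataset = "ds", group = "positive") {
  tibble::tibble(dataset = dataset, group = group,
                 id = paste0(dataset, "_", seq_along(seqs)),
                 sequence = toupper(seqs), length = nchar(seqs))
}

# Hand-built diamond DAG: root -> a -> c and root -> c (plus branch b).
diamond_ontology <- function(namespace = "molecular_function") {
  ontology_from_tables(
    terms = tibble::tibble(
      term = c("D:root", "D:a", "D:b", "D:c"),
      name = c("root", "node a", "node b", "node c"),
      namespace = namespace),
    edges = tibble::tibble(child = c("D:a", "D:b", "D:c", "D:c"),
                           parent = c("D:root", "D:root", "D:a", "D:root"))
  )
}

# Brute-force one-sided hypergeometric tail probability for a 2x2 table,
# by direct enumeration of the support with choose() — independent of
# phyper.
brute_fisher <- function(a, b, c, d) {
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) return(1)
  K <- a + c; n1 <- a + b; N <- a + b + c + d
  support <- max(0, K - (N - n1)):min(K, n1)
  pmf <- choose(n1, support) * choose(N - n1, K - support) / choose(N, K)
  if (a / n1 >= c / (c + d)) sum(pmf[support >= a]) else sum(pmf[support <= a])
}

# Exhaustive concordant-pair AUC.
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# Exact two-sided MWW p by full enumeration of group assignments
# (tie-free data only; feasible for small n).
brute_mww <- function(pos, neg) {
  pooled <- c(pos, neg)
  n1 <- length(pos)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) {
    sum(rank(pooled)[ix]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * (length(neg)) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}
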