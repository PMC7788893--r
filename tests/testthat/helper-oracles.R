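# Independent brute-force oracles. Deliberately un-vectorized, nested-loop
# evaluations of the definitions, kept free of any package internals.

# specificity[g, c] = min over r != c of mean[g, c] / mean[g, r]
# x/0 (x > 0) -> Inf; 0/0 -> skipped; all references skipped -> NA
oracle_specificity <- function(means) {
  k <- ncol(means)
  out <- matrix(NA_real_, nrow(means), k, dimnames = dimnames(means))
  for (g in seq_len(nrow(means))) {
    for (c in seq_len(k)) {
      best <- Inf
      any_defined <- FALSE
      for (r in seq_len(k)) {
        if (r == c) next
        num <- means[g, c]
        den <- means[g, r]
        if (num == 0 && den == 0) next
        ratio <- if (den == 0) Inf else num / den
        any_defined <- TRUE
        if (ratio < best) best <- ratio
      }
      out[g, c] <- if (any_defined) best else NA_real_
    }
  }
  out
}

# type-7 quantile by the textbook formula, scalar
oracle_q7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (h == lo) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# score[g, c] = (spec[g, c] - median_g) / IQR_g over the non-NA row entries;
# all-NA when < 2 entries, IQR 0, or non-finite median/IQR
oracle_score <- function(spec) {
  out <- spec
  out[] <- NA_real_
  for (g in seq_len(nrow(spec))) {
    row <- spec[g, ]
    vals <- row[!is.na(row)]
    if (length(vals) < 2) next
    med <- oracle_q7(vals, 0.5)
    iqr <- oracle_q7(vals, 0.75) - oracle_q7(vals, 0.25)
    if (!is.finite(med) || !is.finite(iqr) || iqr == 0) next
    for (c in seq_len(ncol(spec)))
      if (!is.na(row[c])) out[g, c] <- (row[c] - med) / iqr
  }
  out
}

# Benjamini-Hochberg step-up by direct definition: q_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  running <- adj
  for (i in rev(seq_len(m - 1))) running[i] <- min(running[i], running[i + 1])
  q[ord] <- pmin(running, 1)
  q
}

# exact expectation of the largest connected component among all size-t
# vertex subsets of a small graph, by exhaustive enumeration with igraph
oracle_lcc_expectation <- function(net, t) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$vertices)
  draws <- utils::combn(net$vertices, t)
  sizes <- apply(draws, 2, function(vs)
    max(igraph::components(igraph::induced_subgraph(g, vs))$csize))
  list(mean = mean(sizes), var = stats::var(sizes), n_draws = ncol(draws))
}

# igraph route for the largest component among a vertex subset (cross-check
# for the package's union-find inner loop)
oracle_lcc <- function(net, vs) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$vertices)
  max(igraph::components(igraph::induced_subgraph(g, vs))$csize)
}
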