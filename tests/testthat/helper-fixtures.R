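# Small in-code fixtures shared across test files.

make_expr <- function(values, genes = NULL, cells = NULL, unit = "counts") {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(cells)) cells <- paste0("c", seq_len(ncol(values)))
  expression_matrix(values, genes, cells, unit)
}

make_means <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("t", seq_len(ncol(m)))
  structure(list(genes = rownames(m), types = colnames(m), means = m,
                 n_cells = stats::setNames(rep(1L, ncol(m)), colnames(m))),
            class = "mean_expression")
}

make_net <- function(from, to, weight = NULL, vertices = NULL) {
  if (is.null(weight)) weight <- rep(1, length(from))
  gene_network(data.frame(from = from, to = to, weight = weight),
               vertices = vertices)
}

# random score matrix with a chosen NA fraction
random_scores <- function(n_genes, types, na_frac = 0, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * length(types)), n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), types))
    if (na_frac > 0) m[runif(length(m)) < na_frac] <- NA
    m
  })
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
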