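#' Cell type-specificity: minimum fold change across reference types
#'
#' For gene `g` and cell type `c`, specificity is the minimum over every other
#' type `r` of the ratio of mean expression, `mean[g, c] / mean[g, r]`.
#' A gene highly expressed in `c` relative to every other type gets a large
#' specificity; a value of 1 means the gene is no more expressed in `c` than
#' in its closest competitor.
#'
#' Ratio conventions for zero means: `x / 0` with `x > 0` is `+Inf` (a
#' candidate that only survives the minimum if every reference mean is zero);
#' `0 / 0` is undefined and that reference is skipped; if every reference is
#' undefined the specificity is `NA`. A gene expressed exclusively in `c`
#' therefore keeps specificity `+Inf` instead of being discarded.
#'
#' @param means a `mean_expression` from [mean_by_cell_type()].
#' @return An object of class `specificity_table` with a genes x k
#'   `specificity` matrix (values in `[0, Inf]` or `NA`).
#' @export
compute_specificity <- function(means) {
  stopifnot(inherits(means, "mean_expression"))
  k <- length(means$types)
  if (k < 2L) stop("specificity needs at least 2 cell types")
  m <- means$means
  spec <- matrix(NA_real_, nrow(m), k, dimnames = dimnames(m))
  for (ci in seq_len(k)) {
    ratios <- matrix(NA_real_, nrow(m), k - 1L)
    ri <- 0L
    for (rj in seq_len(k)[-ci]) {
      ri <- ri + 1L
      r <- m[, ci] / m[, rj]          # 0/0 -> NaN, x/0 -> Inf
      r[is.nan(r)] <- NA_real_
      ratios[, ri] <- r
    }
    all_na <- rowSums(!is.na(ratios)) == 0L
    s <- suppressWarnings(apply(ratios, 1L, min, na.rm = TRUE))
    s[all_na] <- NA_real_
    spec[, ci] <- s
  }
  structure(list(genes = means$genes, types = means$types, specificity = spec),
            class = "specificity_table")
}

#' @export
print.specificity_table <- function(x, ...) {
  cat("specificity_table: ", length(x$genes), " genes x ", length(x$types),
      " cell types (", sum(is.na(x$specificity)), " NA entries)\n", sep = "")
  invisible(x)
}

# type-7 quantile that is safe when infinities are present: when the
# interpolation weight is 0 the lower order statistic is returned directly,
# avoiding 0 * Inf. Matches stats::quantile(type = 7) on finite data.
quantile7 <- function(x, p) {
  n <- length(x)
  x <- sort(x)  # Inf sorts last
  idx <- 1 + (n - 1) * p
  lo <- floor(idx)
  h <- idx - lo
  ifelse(h == 0, x[lo], (1 - h) * x[lo] + h * x[pmin(lo + 1, n)])
}

#' Cell-type score: robust standardization of specificity
#'
#' Standardizes each gene's specificity against its own distribution across
#' cell types: `score[g, c] = (specificity[g, c] - median_g) / IQR_g`, with
#' the per-gene median and interquartile range taken over the gene's non-NA
#' specificities (linear-interpolation, type-7 quantiles). A positive score
#' means the gene is more specific to `c` than to its median cell type; at
#' most `floor(k / 2)` types can score positive for any gene.
#'
#' Rows with fewer than two non-NA specificities, a zero IQR, or a non-finite
#' median/IQR (infinite specificities dominating the quartiles) get all-NA
#' scores; an exclusive marker with `specificity = +Inf` but finite median and
#' IQR keeps score `+Inf`, passing any finite threshold.
#'
#' @param spec a `specificity_table` from [compute_specificity()].
#' @return An object of class `score_table` with a genes x k `score` matrix
#'   and the source table in `$provenance`.
#' @export
compute_score <- function(spec) {
  stopifnot(inherits(spec, "specificity_table"))
  s <- spec$specificity
  score <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  n_degenerate <- 0L
  for (g in seq_len(nrow(s))) {
    row <- s[g, ]
    ok <- !is.na(row)
    if (sum(ok) < 2L) next
    med <- quantile7(row[ok], 0.5)
    iqr <- quantile7(row[ok], 0.75) - quantile7(row[ok], 0.25)
    if (!is.finite(med) || !is.finite(iqr) || iqr == 0) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    score[g, ok] <- (row[ok] - med) / iqr
  }
  if (n_degenerate > 0L)
    message(n_degenerate, " gene(s) with zero or non-finite specificity IQR; ",
            "their scores are NA")
  structure(list(genes = spec$genes, types = spec$types, score = score,
                 provenance = spec),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table: ", length(x$genes), " genes x ", length(x$types),
      " cell types (", sum(is.na(x$score)), " NA entries)\n", sep = "")
  invisible(x)
}

#' Assemble a score table from externally computed scores
#'
#' The subnetwork-extraction step only needs per-gene, per-type scores, so
#' any tissue/cell-type specificity metric computed elsewhere can be plugged
#' in through this constructor (or via the TSV reader [read_score_table()]).
#'
#' @param score genes x k numeric matrix with gene row names and cell-type
#'   column names; `NA` allowed.
#' @param specificity optional matching specificity matrix, kept as provenance.
#' @return A `score_table`.
#' @export
score_table <- function(score, specificity = NULL) {
  if (is.null(rownames(score)) || is.null(colnames(score)))
    stop("score matrix needs gene row names and cell-type column names")
  prov <- if (!is.null(specificity))
    structure(list(genes = rownames(score), types = colnames(score),
                   specificity = specificity),
              class = "specificity_table")
  structure(list(genes = rownames(score), types = colnames(score),
                 score = score, provenance = prov),
            class = "score_table")
}

#' Spearman correlation of scores between cell types
#'
#' For every pair of cell types, the Spearman rank correlation of gene scores
#' over the genes with non-NA scores in both members of the pair (average
#' ranks under ties). Pairs sharing fewer than 3 such genes get `NA` with a
#' warning.
#'
#' @param scores a `score_table`.
#' @return Symmetric k x k correlation matrix with unit diagonal.
#' @export
score_correlation <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  k <- length(scores$types)
  out <- diag(1, k)
  dimnames(out) <- list(scores$types, scores$types)
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    x <- scores$score[, i]
    y <- scores$score[, j]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3L) {
      warning("cell types ", scores$types[i], " and ", scores$types[j],
              " share fewer than 3 scored genes; correlation is NA")
      out[i, j] <- out[j, i] <- NA_real_
    } else {
      out[i, j] <- out[j, i] <-
        stats::cor(x[ok], y[ok], method = "spearman")
    }
  }
  out
}

#' Write a score table as tidy TSV
#'
#' One row per gene x cell type with non-NA specificity (or non-NA score when
#' no specificity provenance exists): columns `gene`, `cell_type`,
#' `specificity`, `score`, `NA` rendered literally.
#'
#' @param scores a `score_table`.
#' @param path output path.
#' @export
write_score_table <- function(scores, path) {
  stopifnot(inherits(scores, "score_table"))
  spec <- if (!is.null(scores$provenance)) scores$provenance$specificity
  long <- expand.grid(gene = scores$genes, cell_type = scores$types,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$specificity <- if (!is.null(spec)) as.vector(spec) else NA_real_
  long$score <- as.vector(scores$score)
  keep <- if (!is.null(spec)) !is.na(long$specificity) else !is.na(long$score)
  utils::write.table(long[keep, ], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a tidy score TSV back into a score table
#'
#' Accepts the format written by [write_score_table()] — and therefore score
#' tables produced by any external specificity metric in the same shape.
#'
#' @param path TSV with columns `gene`, `cell_type`, `score` and optionally
#'   `specificity`.
#' @return A `score_table`; gene x type combinations absent from the file are
#'   `NA`.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "cell_type", "score")
  if (!all(need %in% names(tab)))
    stop("score TSV must have columns: ", paste(need, collapse = ", "))
  genes <- unique(tab$gene)
  types <- unique(tab$cell_type)
  sc <- matrix(NA_real_, length(genes), length(types),
               dimnames = list(genes, types))
  sc[cbind(match(tab$gene, genes), match(tab$cell_type, types))] <- tab$score
  spec <- NULL
  if ("specificity" %in% names(tab)) {
    spec <- sc
    spec[] <- NA_real_
    spec[cbind(match(tab$gene, genes), match(tab$cell_type, types))] <-
      tab$specificity
  }
  score_table(sc, spec)
}
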