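# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library users' simulations are not disturbed.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Load a disease-associated gene list
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored, duplicates removed keeping the first occurrence (count logged).
#'
#' @param path input path.
#' @return Character vector of unique gene symbols in file order.
#' @export
load_disease_genes <- function(path) {
  if (!file.exists(path)) stop("disease gene list not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("disease gene list is empty: ", path)
  n_dup <- sum(duplicated(lines))
  if (n_dup > 0L) message(n_dup, " duplicate gene symbol(s) removed")
  unique(lines)
}

#' Candidate disease gene modules of a cell type-specific network
#'
#' Maps the disease genes onto the network (T = number of disease genes
#' present among the network's vertices) and returns the connected components
#' of the subgraph induced by the mapped genes, the candidate disease gene
#' modules, largest first.
#'
#' @param ctn a `cell_type_network` (any `gene_network` is accepted).
#' @param disease_genes character vector of disease-associated gene symbols.
#' @param min_module_size smallest component reported (default 2: an isolated
#'   disease gene is not a module; set 1 to count singletons).
#' @return List with `t` (mapped disease gene count), `mapped` (the genes) and
#'   `modules`, a list of `candidate_module` objects (`genes`, `edges`,
#'   `size`, `cell_type`), sorted by decreasing size then first gene.
#' @export
candidate_modules <- function(ctn, disease_genes, min_module_size = 2L) {
  stopifnot(inherits(ctn, "gene_network"))
  mapped <- intersect(ctn$vertices, unique(disease_genes))
  cell_type <- if (!is.null(ctn$cell_type)) ctn$cell_type else NA_character_
  if (!length(mapped)) {
    warning("no disease genes present in the network",
            if (!is.na(cell_type)) paste0(" (", cell_type, ")"))
    return(list(t = 0L, mapped = character(), modules = list()))
  }
  keep <- ctn$edges$from %in% mapped & ctn$edges$to %in% mapped
  sub <- igraph::graph_from_data_frame(
    ctn$edges[keep, c("from", "to", "weight"), drop = FALSE],
    directed = FALSE, vertices = mapped)
  comp <- igraph::components(sub)
  mods <- lapply(which(comp$csize >= min_module_size), function(ci) {
    genes <- sort(names(comp$membership)[comp$membership == ci])
    e <- ctn$edges[keep & ctn$edges$from %in% genes, , drop = FALSE]
    structure(list(cell_type = cell_type, genes = genes, edges = e,
                   size = length(genes)),
              class = "candidate_module")
  })
  ord <- order(-vapply(mods, `[[`, 0L, "size"),
               vapply(mods, function(m) m$genes[1L], ""))
  list(t = length(mapped), mapped = mapped, modules = mods[ord])
}

#' @export
print.candidate_module <- function(x, ...) {
  cat("candidate_module (", x$cell_type, "): ", x$size, " genes, ",
      nrow(x$edges), " interactions\n", sep = "")
  invisible(x)
}

# Size of the largest connected component among the vertices flagged in the
# logical vector `inset`, given integer edge endpoints (ei, ej). Union-find
# with path halving; isolated selected vertices count as components of size 1.
largest_component_sampled <- function(inset, ei, ej) {
  sel <- which(inset[ei] & inset[ej])
  t_sel <- sum(inset)
  if (t_sel == 0L) return(0L)
  if (!length(sel)) return(1L)
  parent <- seq_along(inset)
  for (e in sel) {
    a <- ei[e]; b <- ej[e]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) parent[b] <- a
  }
  roots <- which(inset)
  for (i in seq_along(roots)) {
    a <- roots[i]
    while (parent[a] != a) a <- parent[a]
    roots[i] <- a
  }
  max(tabulate(roots))
}

#' Permutation null of the largest connected component
#'
#' Null model for disease-module significance: assuming disease genes do not
#' preferentially interact in the cell type-specific network, draw `t` genes
#' uniformly without replacement from the network's vertex set and record the
#' size of the largest connected component among them, `n_perm` times.
#'
#' @param ctn a `cell_type_network` (any `gene_network` is accepted).
#' @param t draw size — the number of disease genes mapped onto the network.
#' @param n_perm number of replicates (default 1000).
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return An object of class `permutation_null` with fields `t`, `s_rand`
#'   (length `n_perm`), `n_perm` and `seed`.
#' @export
permutation_null <- function(ctn, t, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(ctn, "gene_network"))
  nv <- length(ctn$vertices)
  if (t < 1L || t > nv)
    stop("t must be between 1 and the number of vertices (", nv, "), got ", t)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  ei <- match(ctn$edges$from, ctn$vertices)
  ej <- match(ctn$edges$to, ctn$vertices)
  s_rand <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      inset <- logical(nv)
      inset[sample.int(nv, t)] <- TRUE
      as.integer(largest_component_sampled(inset, ei, ej))
    }, integer(1L))
  })
  structure(list(t = as.integer(t), s_rand = s_rand,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("permutation_null: t = ", x$t, ", ", x$n_perm, " replicates (seed ",
      x$seed, "); S_rand mean ", round(mean(x$s_rand), 3), ", max ",
      max(x$s_rand), "\n", sep = "")
  invisible(x)
}

#' Permutation p-value of an observed module size
#'
#' The fraction of null replicates whose largest random component is strictly
#' larger than the observed module: `p = #\{S_rand > S_obs\} / n_perm`.
#' With `pseudocount = TRUE` the estimator `(n + 1) / (n_perm + 1)` is used
#' instead, guaranteeing p > 0.
#'
#' @param s_obs observed module size.
#' @param null a `permutation_null`.
#' @param pseudocount use the add-one estimator (default `FALSE`).
#' @return The p-value, a multiple of `1 / n_perm` (plain estimator).
#' @export
permutation_pvalue <- function(s_obs, null, pseudocount = FALSE) {
  stopifnot(inherits(null, "permutation_null"))
  n <- sum(null$s_rand > s_obs)
  if (pseudocount) (n + 1) / (null$n_perm + 1) else n / null$n_perm
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment, returned in the input order, capped at 1.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Identify significant cell type-specific disease gene modules
#'
#' For each cell type-specific network: map the disease genes, enumerate
#' candidate modules (connected components), build one permutation null per
#' network at its mapped gene count T, compute per-candidate p-values, and
#' apply Benjamini-Hochberg FDR control. By default the correction pools all
#' candidates across cell types of the run (`fdr_scope = "global"`);
#' `"per-cell-type"` corrects within each network instead.
#'
#' @param ctn_per_type named list of `cell_type_network` objects (names are
#'   used as cell-type labels if the networks carry none).
#' @param disease_genes character vector of disease-associated genes.
#' @param n_perm permutation replicates per network (default 1000).
#' @param seed RNG seed; nulls are drawn sequentially from one stream seeded
#'   once, so the full report is reproducible.
#' @param fdr_cutoff significance is declared at q < `fdr_cutoff`
#'   (default 0.1).
#' @param min_module_size smallest candidate reported (default 2).
#' @param fdr_scope `"global"` or `"per-cell-type"`.
#' @param pseudocount passed to [permutation_pvalue()].
#' @return A `module_report`: data.frame with one row per candidate module
#'   (`cell_type`, `module_id`, `size`, `t`, `p_perm`, `q_fdr`,
#'   `significant`, `genes` semicolon-joined), ordered by cell type then
#'   decreasing size, with the run parameters in `attr(, "parameters")` and
#'   the module objects in `attr(, "modules")`.
#' @export
identify_modules <- function(ctn_per_type, disease_genes, n_perm = 1000L,
                             seed = 1L, fdr_cutoff = 0.1,
                             min_module_size = 2L,
                             fdr_scope = c("global", "per-cell-type"),
                             pseudocount = FALSE) {
  fdr_scope <- match.arg(fdr_scope)
  if (!length(ctn_per_type)) stop("at least one cell type network is required")
  if (is.null(names(ctn_per_type)))
    names(ctn_per_type) <- vapply(ctn_per_type, function(n)
      if (!is.null(n$cell_type)) n$cell_type else NA_character_, "")
  rows <- list()
  all_modules <- list()
  for (idx in seq_along(ctn_per_type)) {
    ctn <- ctn_per_type[[idx]]
    ty <- names(ctn_per_type)[idx]
    cand <- withCallingHandlers(
      candidate_modules(ctn, disease_genes, min_module_size),
      warning = function(w) {
        message("note [", ty, "]: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (!length(cand$modules)) next
    # one null per (cell type, T): T is shared by all candidates here
    null <- permutation_null(ctn, cand$t, n_perm = n_perm,
                             seed = seed + idx - 1L)
    for (mi in seq_along(cand$modules)) {
      mod <- cand$modules[[mi]]
      mod$cell_type <- ty
      id <- paste0(ty, ".m", mi)
      all_modules[[id]] <- mod
      rows[[id]] <- data.frame(
        cell_type = ty, module_id = id, size = mod$size, t = cand$t,
        p_perm = permutation_pvalue(mod$size, null, pseudocount),
        genes = paste(mod$genes, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(), module_id = character(),
               size = integer(), t = integer(), p_perm = numeric(),
               genes = character(), stringsAsFactors = FALSE)
  if (nrow(report)) {
    report$q_fdr <- if (fdr_scope == "global") bh_adjust(report$p_perm) else
      stats::ave(report$p_perm, report$cell_type, FUN = bh_adjust)
    report$significant <- report$q_fdr < fdr_cutoff
  } else {
    report$q_fdr <- numeric()
    report$significant <- logical()
  }
  report <- report[, c("cell_type", "module_id", "size", "t", "p_perm",
                       "q_fdr", "significant", "genes")]
  rownames(report) <- NULL
  structure(report,
            class = c("module_report", "data.frame"),
            parameters = list(n_perm = as.integer(n_perm),
                              seed = as.integer(seed),
                              fdr_cutoff = fdr_cutoff,
                              min_module_size = as.integer(min_module_size),
                              fdr_scope = fdr_scope,
                              pseudocount = pseudocount),
            modules = all_modules)
}

#' @export
print.module_report <- function(x, ...) {
  p <- attr(x, "parameters")
  cat("module_report: ", nrow(x), " candidate module(s), ",
      sum(x$significant), " significant at FDR < ", p$fdr_cutoff,
      " (", p$n_perm, " permutations, seed ", p$seed, ")\n", sep = "")
  if (nrow(x)) {
    show <- x
    show$genes <- ifelse(nchar(show$genes) > 40,
                         paste0(substr(show$genes, 1, 37), "..."), show$genes)
    print.data.frame(show, row.names = FALSE)
  }
  invisible(x)
}

#' Write a module report (TSV plus JSON parameter sidecar)
#'
#' @param report a `module_report`.
#' @param path output TSV path; `<path>.params.json` records the run
#'   parameters; per-module edge lists go to `<path>.<module_id>.edges.tsv`
#'   when `edges = TRUE`.
#' @param edges also write per-module induced edge lists (default `FALSE`).
#' @export
write_module_report <- function(report, path, edges = FALSE) {
  stopifnot(inherits(report, "module_report"))
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(attr(report, "parameters"),
                       paste0(path, ".params.json"), auto_unbox = TRUE)
  if (edges)
    for (id in names(attr(report, "modules"))) {
      e <- attr(report, "modules")[[id]]$edges
      utils::write.table(e, paste0(path, ".", id, ".edges.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  invisible(path)
}
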