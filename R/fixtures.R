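#' Simulate cell-annotated count data with planted cell-type markers
#'
#' Background counts for every gene and cell are drawn from a negative
#' binomial with a common mean; each cell type gets a disjoint block of
#' planted marker genes whose mean is multiplied by `fold` in their home type
#' only. As `dispersion` approaches 0 the counts become Poisson and, with many
#' cells per type, a planted marker's specificity in its home type converges
#' to `fold`.
#'
#' @param n_genes total genes.
#' @param k number of cell types (labeled ct1..ctk).
#' @param cells_per_type cells per type.
#' @param marker_frac fraction of genes planted as markers in each type;
#'   `marker_frac * n_genes >= 1` and the `k` marker blocks must fit.
#' @param fold fold change of a marker's mean in its home type (> 1).
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2); 0 gives Poisson counts.
#' @param base_mean background mean count per gene per cell.
#' @param seed RNG seed; caller's RNG state is untouched.
#' @return List with `expr` (an [expression_matrix()], unit counts), `ann`
#'   (a `cell_annotation`) and `truth` (planted markers per type, parameters,
#'   seed).
#' @export
simulate_expression <- function(n_genes = 1000L, k = 4L, cells_per_type = 60L,
                                marker_frac = 0.05, fold = 4,
                                dispersion = 0.3, base_mean = 5, seed = 1L) {
  if (fold <= 1) stop("fold must be > 1")
  n_markers <- floor(marker_frac * n_genes)
  if (n_markers < 1L) stop("marker_frac * n_genes must be at least 1")
  if (n_markers * k > n_genes)
    stop("marker blocks (", n_markers * k, " genes) exceed n_genes")
  if (dispersion < 0) stop("dispersion must be >= 0")
  genes <- sprintf("g%04d", seq_len(n_genes))
  types <- paste0("ct", seq_len(k))
  cells <- sprintf("cell%04d", seq_len(k * cells_per_type))
  type_of <- rep(types, each = cells_per_type)
  markers <- stats::setNames(lapply(seq_len(k), function(i)
    genes[seq((i - 1L) * n_markers + 1L, i * n_markers)]), types)
  mu <- matrix(base_mean, n_genes, length(cells), dimnames = list(genes, cells))
  for (ty in types)
    mu[markers[[ty]], type_of == ty] <- base_mean * fold
  counts <- with_seed(seed, {
    if (dispersion == 0)
      matrix(stats::rpois(length(mu), mu), n_genes, dimnames = dimnames(mu))
    else
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_genes, dimnames = dimnames(mu))
  })
  # guard against all-zero cells at tiny parameter settings
  zero <- Matrix::colSums(counts) == 0
  counts[1L, zero] <- 1
  list(expr = expression_matrix(counts, genes, cells, "counts"),
       ann = cell_annotation(stats::setNames(type_of, cells)),
       truth = list(planted_markers = markers, fold = fold,
                    params = list(n_genes = n_genes, k = k,
                                  cells_per_type = cells_per_type,
                                  marker_frac = marker_frac,
                                  dispersion = dispersion,
                                  base_mean = base_mean),
                    seed = seed))
}

#' Simulate a random gene network with a planted disease module
#'
#' Background edges are sampled uniformly among all vertex pairs
#' (Erdős–Rényi-style); `module_size` of the disease genes are additionally
#' connected by a random spanning tree, guaranteeing a connected disease
#' component of at least the planted genes. Remaining disease genes are
#' scattered uniformly. Weights are uniform on (0, 1].
#'
#' @param n_vertices total genes in the network.
#' @param n_edges background edges to sample (before merging with the planted
#'   tree; duplicates keep one copy).
#' @param module_size planted connected disease genes (0 for a null network
#'   with no planted structure); ignored when `planted_genes` is given.
#' @param n_disease_genes total disease genes, `>= module_size`.
#' @param seed RNG seed; caller's RNG state is untouched.
#' @param genes optional explicit vertex names (e.g. the genes of a simulated
#'   expression matrix, so the pipeline's gene-intersection step keeps the
#'   network); overrides `n_vertices`.
#' @param planted_genes optional explicit planted-module gene set (e.g. one
#'   cell type's planted markers, so the module survives score thresholding);
#'   must be a subset of the vertex names.
#' @return List with `net` (a `gene_network`), `disease_genes` (character)
#'   and `truth` (`planted_module` genes, parameters, seed).
#' @export
simulate_network <- function(n_vertices = 500L, n_edges = 1250L,
                             module_size = 10L, n_disease_genes = 30L,
                             seed = 1L, genes = NULL, planted_genes = NULL) {
  if (is.null(genes)) genes <- sprintf("v%04d", seq_len(n_vertices))
  n_vertices <- length(genes)
  if (!is.null(planted_genes)) {
    if (!all(planted_genes %in% genes))
      stop("planted_genes must be a subset of the vertex names")
    module_size <- length(planted_genes)
  }
  if (n_disease_genes > n_vertices)
    stop("n_disease_genes exceeds n_vertices")
  if (module_size > n_disease_genes)
    stop("module_size exceeds n_disease_genes")
  if (module_size > 1L && n_edges < module_size - 1L)
    stop("n_edges must be at least module_size - 1")
  max_edges <- n_vertices * (n_vertices - 1) / 2
  if (n_edges > max_edges) stop("n_edges exceeds the number of vertex pairs")
  sim <- with_seed(seed, {
    planted <- if (!is.null(planted_genes)) as.character(planted_genes)
      else if (module_size > 0L) sample(genes, module_size) else character()
    disease <- c(planted,
                 sample(setdiff(genes, planted),
                        n_disease_genes - length(planted)))
    # uniform pair sampling via linear pair indices
    pid <- sample(max_edges, n_edges)
    i <- ceiling((sqrt(8 * (pid - 0.5) + 1) - 1) / 2) + 1
    j <- pid - (i - 1) * (i - 2) / 2
    bg <- data.frame(from = genes[j], to = genes[i],
                     stringsAsFactors = FALSE)
    tree <- NULL
    if (module_size > 1L) {
      ord <- sample(planted)
      tree <- data.frame(
        from = vapply(2:module_size,
                      function(t) ord[sample.int(t - 1L, 1L)], ""),
        to = ord[-1L], stringsAsFactors = FALSE)
    }
    edges <- rbind(bg, tree)
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ]
    edges$weight <- stats::runif(nrow(edges))
    list(edges = edges, disease = disease, planted = planted)
  })
  net <- gene_network(sim$edges, vertices = genes, label = "synthetic")
  list(net = net, disease_genes = sim$disease,
       truth = list(planted_module = sim$planted,
                    params = list(n_vertices = n_vertices, n_edges = n_edges,
                                  module_size = module_size,
                                  n_disease_genes = n_disease_genes),
                    seed = seed))
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the exact on-disk formats the pipeline consumes: an MTX count matrix
#' with gene/cell sidecars, the annotation TSV, the network edge-list TSV,
#' the disease-gene list, and a ground-truth JSON recording the planted
#' markers and module.
#'
#' @param dir output directory (created if needed).
#' @param expr_sim result of [simulate_expression()].
#' @param net_sim result of [simulate_network()].
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixtures <- function(dir, expr_sim, net_sim) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(dir, "counts.mtx"),
    genes = file.path(dir, "genes.txt"),
    cells = file.path(dir, "cells.txt"),
    annotation = file.path(dir, "annotation.tsv"),
    network = file.path(dir, "network.tsv"),
    disease = file.path(dir, "disease_genes.txt"),
    truth = file.path(dir, "truth.json"))
  Matrix::writeMM(methods::as(methods::as(expr_sim$expr$values, "CsparseMatrix"),
                              "generalMatrix"), paths$matrix)
  writeLines(expr_sim$expr$genes, paths$genes)
  writeLines(expr_sim$expr$cells, paths$cells)
  utils::write.table(
    data.frame(cell_id = names(expr_sim$ann$cell_to_type),
               cell_type = unname(expr_sim$ann$cell_to_type)),
    paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(net_sim$net, paths$network, vertices_path = NA)
  writeLines(net_sim$disease_genes, paths$disease)
  jsonlite::write_json(list(expression = expr_sim$truth,
                            network = net_sim$truth),
                       paths$truth, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
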