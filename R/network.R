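#' Construct a gene network
#'
#' Undirected weighted gene network stored as a canonical edge list: each
#' unordered pair appears once as `(min(u, v), max(u, v))`, self-loops are
#' forbidden, weights are finite and nonnegative. The vertex set is the union
#' of edge endpoints plus any explicitly retained isolated genes.
#'
#' @param edges data.frame with columns `from`, `to`, `weight`.
#' @param vertices optional character vector of vertices to retain even if
#'   isolated; always extended with the edge endpoints.
#' @param label free-text provenance string.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges, vertices = NULL, label = "") {
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and nonnegative")
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (anyDuplicated(paste(edges$from, edges$to, sep = "\r")))
    stop("duplicate edges; use load_network() to canonicalize raw edge lists")
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  verts <- sort(unique(c(edges$from, edges$to, as.character(vertices))))
  structure(list(edges = edges, vertices = verts, label = label),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(class(x)[1L], ": ", length(x$vertices), " genes, ", nrow(x$edges),
      " interactions", if (nzchar(x$label)) paste0(" [", x$label, "]"),
      "\n", sep = "")
  if (inherits(x, "cell_type_network"))
    cat("  cell type: ", x$cell_type, ", score threshold: ", x$threshold,
        "\n", sep = "")
  invisible(x)
}

#' Number of edges / vertices of a gene network
#' @param net a `gene_network`.
#' @return Integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_vertices <- function(net) length(net$vertices)

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$vertices)
  g
}

#' Load a weighted gene network from a 3-column edge list
#'
#' Reads a whitespace/tab-delimited file with columns gene1, gene2, weight
#' (the layout of the GIANT tissue-network downloads), transparently
#' decompressing `.gz`. Edges are canonicalized as unordered pairs; duplicate
#' pairs keep the maximum weight and self-loops are dropped, both with a
#' logged count.
#'
#' @param path edge-list path, optionally gzip-compressed.
#' @param label provenance label stored on the network (defaults to the
#'   file name).
#' @return A `gene_network`.
#' @export
load_network <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("network file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  tab <- utils::read.table(con, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("from", "to", "weight"),
                           colClasses = c("character", "character", "character"))
  w <- suppressWarnings(as.numeric(tab$weight))
  if (anyNA(w))
    stop("non-numeric weight at line ", which(is.na(w))[1L], " of ", path)
  tab$weight <- w
  loops <- tab$from == tab$to
  if (any(loops))
    message(sum(loops), " self-loop(s) dropped")
  tab <- tab[!loops, , drop = FALSE]
  if (!nrow(tab)) stop("network has no valid edges: ", path)
  swap <- tab$from > tab$to
  tmp <- tab$from[swap]
  tab$from[swap] <- tab$to[swap]
  tab$to[swap] <- tmp
  key <- paste(tab$from, tab$to, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate edge(s) collapsed (max weight kept)")
    w <- tapply(tab$weight, key, max)
    tab <- tab[!duplicated(key), , drop = FALSE]
    tab$weight <- as.numeric(w[paste(tab$from, tab$to, sep = "\r")])
  }
  gene_network(tab, label = label)
}

#' Write a gene network as a 3-column edge list (plus vertex list)
#'
#' @param net a `gene_network`.
#' @param path output TSV path (`.gz` for gzip); a sibling
#'   `<path>.vertices.txt` one-column file records the full vertex set,
#'   including isolated genes.
#' @param vertices_path override for the vertex-list path; `NULL` for the
#'   default, `NA` to skip writing it.
#' @export
write_network <- function(net, path, vertices_path = NULL) {
  stopifnot(inherits(net, "gene_network"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.table(net$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  if (is.null(vertices_path)) vertices_path <- paste0(path, ".vertices.txt")
  if (!is.na(vertices_path)) writeLines(net$vertices, vertices_path)
  invisible(path)
}

#' Drop the lowest-ranked fraction of edges by weight
#'
#' Edges are ranked ascending by weight (ties broken by the canonical edge
#' key, lexicographically) and the first `floor(drop_fraction * m)` are
#' removed — the reliability filter applied to a reference interactome before
#' subsetting. Vertices are recomputed from the surviving edges.
#'
#' @param net a `gene_network` with at least one edge.
#' @param drop_fraction fraction in `[0, 1)` of edges to remove (default 0.2:
#'   drop the bottom fifth).
#' @return The filtered `gene_network`.
#' @export
filter_by_weight_rank <- function(net, drop_fraction = 0.2) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1)
    stop("drop_fraction must be in [0, 1)")
  m <- nrow(net$edges)
  if (m < 1L) stop("network has no edges")
  n_drop <- floor(drop_fraction * m)
  if (n_drop == 0L) return(net)
  ord <- order(net$edges$weight, net$edges$from, net$edges$to)
  keep <- net$edges[-ord[seq_len(n_drop)], , drop = FALSE]
  message(n_drop, " of ", m, " interaction(s) removed by the weight-rank filter")
  gene_network(keep, label = net$label)
}

#' Induced subnetwork on a gene set
#'
#' Restricts the network to the intersection of its vertices with `genes`:
#' surviving edges have both endpoints in the intersection, and intersection
#' members left without edges are kept as isolated vertices. Used to retain
#' the overlap between the reference network and the measured genes.
#'
#' @param net a `gene_network`.
#' @param genes character vector of gene identifiers.
#' @return The induced `gene_network`.
#' @export
restrict_to_genes <- function(net, genes) {
  stopifnot(inherits(net, "gene_network"))
  keep_v <- intersect(net$vertices, genes)
  if (!length(keep_v))
    stop("no overlap between the network's ", length(net$vertices),
         " genes and the supplied ", length(unique(genes)), " gene(s)")
  keep_e <- net$edges$from %in% keep_v & net$edges$to %in% keep_v
  message(sum(!keep_e), " interaction(s) and ",
          length(net$vertices) - length(keep_v),
          " gene(s) removed by the gene intersection")
  out <- gene_network(net$edges[keep_e, , drop = FALSE], vertices = keep_v,
                      label = net$label)
  out
}

#' Extract a cell type-specific gene network
#'
#' Keeps the genes whose score in `cell_type` strictly exceeds `threshold`
#' (NA scores always fail) together with the interactions among them; genes
#' passing the threshold but left without interactions stay in the vertex set.
#' With nested thresholds t1 <= t2 the t2 network is a subnetwork of the t1
#' network.
#'
#' @param net the (filtered, gene-intersected) reference `gene_network`.
#' @param scores a `score_table` covering `cell_type`.
#' @param cell_type one of `scores$types`.
#' @param threshold score cutoff; positive values keep genes whose
#'   specificity exceeds their own cross-type median (default 0).
#' @return An object of class `cell_type_network` (a `gene_network` carrying
#'   `cell_type`, `threshold` and `score_source`).
#' @export
extract_cell_type_network <- function(net, scores, cell_type, threshold = 0) {
  stopifnot(inherits(net, "gene_network"), inherits(scores, "score_table"))
  if (!cell_type %in% scores$types)
    stop("unknown cell type '", cell_type, "'; available: ",
         paste(scores$types, collapse = ", "))
  s <- scores$score[, cell_type]
  passing <- scores$genes[!is.na(s) & s > threshold]
  keep_v <- intersect(net$vertices, passing)
  keep_e <- net$edges$from %in% keep_v & net$edges$to %in% keep_v
  out <- gene_network(net$edges[keep_e, , drop = FALSE], vertices = keep_v,
                      label = net$label)
  out$cell_type <- cell_type
  out$threshold <- threshold
  out$score_source <- if (!is.null(scores$provenance)) "specificity" else "external"
  class(out) <- c("cell_type_network", class(out))
  out
}

#' Jaccard similarity of two gene sets
#'
#' Intersection over union, used to compare the gene content of cell
#' type-specific networks.
#'
#' @param set_a,set_b character vectors (de-duplicated internally).
#' @return A number in `[0, 1]`, or `NA` with a warning if both sets are
#'   empty.
#' @export
jaccard_similarity <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("both gene sets are empty; Jaccard similarity is NA")
    return(NA_real_)
  }
  length(intersect(a, b)) / u
}
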