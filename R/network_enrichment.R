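#' Correlation network over discriminatory genes
#'
#' Computes pairwise Pearson correlations between the selected genes across
#' all samples and returns either the maximum spanning tree on absolute
#' correlation (default; the most strongly co-expressed backbone) or the
#' graph of all pairs with |r| above a threshold. Edges carry the signed
#' correlation in attribute \code{r} and |r| in \code{absr}. Zero-variance
#' genes are excluded with a warning.
#'
#' @param pe a [PhenotypeExperiment-class] (log2 scale recommended).
#' @param genes character vector of >= 2 probe ids present in \code{pe}.
#' @param method \code{"mst"} (maximum spanning tree) or \code{"threshold"}.
#' @param threshold minimum |r| for an edge when \code{method = "threshold"}.
#' @return An \pkg{igraph} graph with vertex names and edge attributes
#'   \code{r}, \code{absr}; for \code{"mst"} a tree with (nodes - 1) edges.
#' @export
correlationNetwork <- function(pe, genes, method = c("mst", "threshold"),
                               threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(methods::is(pe, "PhenotypeExperiment"))
  missing <- setdiff(genes, probeIds(pe))
  if (length(missing)) {
    stop("genes absent from the experiment: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  }
  x <- exprValues(pe)[genes, , drop = FALSE]
  v <- apply(x, 1L, stats::var)
  if (any(v == 0)) {
    warning("excluding zero-variance gene(s): ",
            paste(genes[v == 0], collapse = ", "))
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 genes with non-zero variance")
  r <- stats::cor(t(x))
  g <- igraph::graph_from_adjacency_matrix(abs(r), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ends <- igraph::ends(g, igraph::E(g))
  igraph::E(g)$r <- r[cbind(ends[, 1L], ends[, 2L])]
  igraph::E(g)$absr <- abs(igraph::E(g)$r)
  if (method == "mst") {
    # minimum spanning tree on (1 - |r|) is the maximum spanning tree on |r|
    g <- igraph::mst(g, weights = 1 - igraph::E(g)$absr)
  } else {
    g <- igraph::subgraph_from_edges(g, igraph::E(g)[igraph::E(g)$absr >= threshold],
                                     delete.vertices = FALSE)
  }
  g
}

#' Write a network as an edge-list TSV
#'
#' Columns \code{geneA}, \code{geneB}, \code{r} (signed Pearson correlation).
#'
#' @param graph an \pkg{igraph} graph from [correlationNetwork()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  ends <- igraph::ends(graph, igraph::E(graph))
  df <- data.frame(geneA = ends[, 1L], geneB = ends[, 2L],
                   r = igraph::E(graph)$r, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated name, description, members.
#'
#' @param path path to a .gmt file.
#' @return Named list of character vectors of gene symbols.
#' @export
readGeneSets <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (length(sets) == 0L || any(lengths(sets) == 0L)) {
    stop("gene-set collection must contain non-empty sets")
  }
  sets
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the gene list within the
#' universe using the hypergeometric upper tail (one-sided Fisher test), with
#' Benjamini-Hochberg adjustment across sets. Sets are intersected with the
#' universe before testing; the gene list must be a subset of the universe.
#' A local stand-in for querying ontological platforms with the most
#' frequently sampled genes.
#'
#' @param geneList character vector of selected gene symbols (non-empty).
#' @param collection named list of gene sets (see [readGeneSets()]).
#' @param universe character vector of all testable symbols (non-empty).
#' @return data.frame sorted by p-value: \code{setName}, \code{overlap},
#'   \code{setSize}, \code{listSize}, \code{universeSize}, \code{pValue},
#'   \code{padj}.
#' @export
overrepresentation <- function(geneList, collection, universe) {
  geneList <- unique(geneList)
  universe <- unique(universe)
  if (length(geneList) == 0L || length(universe) == 0L) {
    stop("gene list and universe must be non-empty")
  }
  if (!all(geneList %in% universe)) {
    stop("gene list must be a subset of the universe")
  }
  N <- length(universe)
  n <- length(geneList)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(set, geneList))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(setName = nm, overlap = k, setSize = K, listSize = n,
               universeSize = N, pValue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pValue, method = "BH")
  out[order(out$pValue, method = "radix"), , drop = FALSE]
}
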