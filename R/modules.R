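#' Aggregated effect matrix of strongly differential genes
#'
#' Builds the genes x coefficients matrix of log2FC values used for module
#' discovery, keeping only genes that are strongly differential (adjusted p
#' below `padj_cut` and absolute log2FC above `lfc_cut`) in at least one
#' coefficient. Coefficients a gene was not tested in are imputed as zero
#' (absence of evidence of effect) with a logged count.
#'
#' @param fits long fit table(s): a data.frame with `gene`, `coefficient`,
#'   `logFC`, `padj`, a `stimsig_fit`, or a (optionally named) list of
#'   either, whose coefficient names are prefixed by the list names.
#' @param padj_cut,lfc_cut the two filter thresholds.
#' @return numeric matrix (genes x coefficients).
#' @export
effect_matrix <- function(fits, padj_cut = 0.05, lfc_cut = 2) {
  tab <- collect_fit_tables(fits)
  hit <- tab$padj < padj_cut & abs(tab$logFC) > lfc_cut
  keep_genes <- unique(tab$gene[hit & !is.na(hit)])
  if (!length(keep_genes)) stop("no gene passes the effect-matrix filter")
  tab <- tab[tab$gene %in% keep_genes, ]
  coefs <- unique(tab$coefficient)
  m <- matrix(NA_real_, length(keep_genes), length(coefs),
              dimnames = list(sort(keep_genes), coefs))
  m[cbind(match(tab$gene, rownames(m)), match(tab$coefficient, coefs))] <- tab$logFC
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    message(n_imputed, " missing log2FC value(s) imputed as 0")
    m[is.na(m)] <- 0
  }
  m
}

collect_fit_tables <- function(fits) {
  one <- function(f, prefix = NULL) {
    tab <- if (inherits(f, "stimsig_fit")) f$table else f
    stopifnot(all(c("gene", "coefficient", "logFC", "padj") %in% colnames(tab)))
    if (!is.null(prefix) && nzchar(prefix)) {
      tab$coefficient <- paste(prefix, tab$coefficient, sep = ".")
    }
    tab[, c("gene", "coefficient", "logFC", "padj")]
  }
  if (inherits(fits, "stimsig_fit") || is.data.frame(fits)) return(one(fits))
  nm <- names(fits)
  if (is.null(nm)) nm <- rep("", length(fits))
  do.call(rbind, Map(one, fits, nm))
}

#' Symmetrized k-nearest-neighbour graph
#'
#' Undirected graph with an edge between two genes whenever either is among
#' the other's `k` nearest neighbours (Euclidean distance on the effect
#' matrix rows). Distance ties are broken by row order, making the graph
#' deterministic.
#'
#' @param mat numeric matrix (genes x coefficients), e.g. from
#'   [effect_matrix()].
#' @param k neighbourhood size; must be smaller than the number of genes.
#' @return an [igraph::graph] with vertex names taken from the rownames.
#' @export
knn_graph <- function(mat, k = 15) {
  n <- nrow(mat)
  if (k >= n) stop("k (", k, ") must be smaller than the number of genes (", n, ")")
  if (k < 1) stop("k must be >= 1")
  d <- as.matrix(stats::dist(mat))
  edges <- matrix(integer(0), ncol = 2)
  nn <- t(vapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))      # tie-break by row order
    setdiff(ord, i)[seq_len(k)]
  }, integer(k)))
  if (k == 1) nn <- matrix(nn, ncol = 1)
  edges <- cbind(rep(seq_len(n), k), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)                # union symmetrization, no self-loops
  igraph::V(g)$name <- rownames(mat)
  g
}

#' Random-walk community detection
#'
#' Communities from short random walks (walktrap agglomeration via
#' [igraph::cluster_walktrap()]), cutting the merge tree at maximum
#' modularity. Isolated vertices form singleton communities.
#'
#' @param graph an undirected [igraph::graph], e.g. from [knn_graph()].
#' @param steps random-walk length (default 4, the walktrap default).
#' @return named integer vector of community memberships.
#' @export
walktrap_communities <- function(graph, steps = 4) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  deg <- igraph::degree(graph)
  memb <- rep(NA_integer_, igraph::vcount(graph))
  names(memb) <- igraph::V(graph)$name
  if (any(deg > 0)) {
    sub <- igraph::induced_subgraph(graph, which(deg > 0))
    wt <- igraph::cluster_walktrap(sub, steps = steps)
    memb[igraph::V(sub)$name] <- igraph::membership(wt)
  }
  iso <- which(deg == 0)
  if (length(iso)) {
    base <- max(memb, 0L, na.rm = TRUE)
    memb[iso] <- base + seq_along(iso)
  }
  memb
}

#' Per-module mean log2FC table
#'
#' Arithmetic mean of each coefficient's log2FC across the genes of every
#' community, with community sizes.
#'
#' @param membership named community vector from [walktrap_communities()].
#' @param mat the effect matrix the communities were derived from.
#' @return data.frame: `module`, `size`, then one column per coefficient.
#' @export
module_mean_lfc <- function(membership, mat) {
  missing_genes <- setdiff(rownames(mat), names(membership))
  if (length(missing_genes)) {
    stop("gene(s) without module assignment: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  memb <- membership[rownames(mat)]
  means <- rowsum(mat, memb) / as.vector(table(memb))
  out <- data.frame(module = rownames(means),
                    size = as.integer(table(memb)),
                    means, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-d^2 / 2` and embeds on the top eigenvectors scaled by
#' the square roots of the eigenvalues (via [stats::cmdscale()]); the
#' configuration is defined up to rotation and reflection.
#'
#' @param d distance matrix (or `dist`).
#' @param k embedding dimension.
#' @return matrix (points x k) of coordinates, eigenvalues in attribute
#'   `eig`.
#' @export
classical_mds <- function(d, k = 2) {
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  structure(fit$points, eig = fit$eig)
}

#' Similarity map of contrasts by MDS of log2FC correlations
#'
#' Distances between contrasts are one minus the Spearman correlation of
#' their log2FC vectors over the shared gene universe; the map is the
#' 2-D classical MDS embedding of those distances.
#'
#' @param lfc genes x contrasts matrix of log2FC values, or a long fit
#'   table / `stimsig_fit` / list of fits (reshaped internally over the
#'   common gene universe).
#' @return data.frame: `contrast`, `dim1`, `dim2`.
#' @export
contrast_similarity_mds <- function(lfc) {
  if (!is.matrix(lfc)) {
    tab <- collect_fit_tables(lfc)
    genes <- sort(unique(tab$gene))
    coefs <- unique(tab$coefficient)
    m <- matrix(NA_real_, length(genes), length(coefs),
                dimnames = list(genes, coefs))
    m[cbind(match(tab$gene, genes), match(tab$coefficient, coefs))] <- tab$logFC
    lfc <- m
  }
  if (ncol(lfc) < 3) stop("need at least 3 contrasts for the similarity map")
  d <- 1 - stats::cor(lfc, method = "spearman", use = "pairwise.complete.obs")
  pts <- classical_mds(d, k = 2)
  data.frame(contrast = colnames(lfc), dim1 = pts[, 1], dim2 = pts[, 2],
             stringsAsFactors = FALSE)
}

#' Two-dimensional layout of the gene graph (visualization only)
#'
#' Convenience Fruchterman-Reingold layout of the kNN graph. The layout is
#' cosmetic: community detection operates on the graph itself and does not
#' depend on these coordinates.
#'
#' @param mat effect matrix (genes x coefficients).
#' @param k neighbourhood size passed to [knn_graph()].
#' @param seed layout seed.
#' @return data.frame: `gene`, `x`, `y`.
#' @export
embed_2d <- function(mat, k = 15, seed = 1L) {
  g <- knn_graph(mat, k = k)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  data.frame(gene = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}
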