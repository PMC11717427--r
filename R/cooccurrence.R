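#' Jaccard distance between two presence vectors
#'
#' `d_J = 1 - |A n B| / |A u B|` where A and B are the sets of lists
#' containing each gene. Both vectors must contain at least one 1 (genes
#' come from an occurrence matrix, so this always holds upstream).
#'
#' @param a,b binary vectors of equal length over the n lists.
#' @return distance in \[0,1\].
#' @export
jaccard_distance <- function(a, b) {
  if (length(a) != length(b)) stop("presence vectors differ in length")
  a <- as.logical(a); b <- as.logical(b)
  if (!any(a) || !any(b)) stop("zero presence vector: Jaccard undefined")
  1 - sum(a & b) / sum(a | b)
}

#' Pairwise Jaccard distance matrix for a gene subset
#'
#' @param m an `occurrence_matrix`.
#' @param genes gene ids (default: all genes in `m`).
#' @return symmetric matrix of Jaccard distances, zero diagonal.
#' @export
jaccard_matrix <- function(m, genes = m$gene_ids) {
  inc <- m$incidence[genes, , drop = FALSE] > 0L
  inter <- tcrossprod(inc * 1L)
  sz <- rowSums(inc)
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) dendrogram from a distance table
#'
#' Agglomerates with mean inter-cluster distance, as produced by
#' `stats::hclust(method = "average")`, and can serialize the result to
#' Newick with branch lengths derived from merge heights.
#'
#' @param d symmetric numeric matrix with zero diagonal (e.g. from
#'   [jaccard_matrix()]).
#' @param newick optional path; when given, the tree is written in Newick
#'   format via \pkg{ape}.
#' @return an `hclust` object.
#' @export
average_linkage_tree <- function(d, newick = NULL) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance table not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance table diagonal not zero")
  hc <- hclust(as.dist(d), method = "average")
  if (!is.null(newick))
    ape::write.tree(ape::as.phylo(hc), file = newick)
  hc
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Historical mutual information between two presence vectors
#'
#' Symmetric normalized mutual information of the 2x2 contingency of two
#' genes' presence/absence across the n lists. The default normalization is
#' the symmetric uncertainty `2 I(A;B) / (H(A) + H(B))`; the geometric form
#' `I / sqrt(H(A) H(B))` is available via `normalization = "geometric"`.
#' Defined as 0 when the marginal entropies vanish (constant vectors);
#' `0 log 0 = 0` throughout. The measure is "historical" in that it reflects
#' both functional relatedness and the field's biased sampling of genes.
#'
#' @param a,b binary vectors of equal length.
#' @param normalization `"symmetric"` (default) or `"geometric"`.
#' @return a value in \[0,1\], symmetric in its arguments.
#' @export
hmi <- function(a, b, normalization = c("symmetric", "geometric")) {
  if (length(a) != length(b)) stop("presence vectors differ in length")
  normalization <- match.arg(normalization)
  n <- length(a)
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  joint <- table(factor(a, levels = 0:1), factor(b, levels = 0:1)) / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ha <- entropy2(pa); hb <- entropy2(pb)
  I <- 0
  for (i in 1:2) for (j in 1:2) {
    pij <- joint[i, j]
    if (pij > 0) I <- I + pij * log(pij / (pa[i] * pb[j]))
  }
  I <- max(I, 0)  # guard tiny negative rounding
  denom <- if (normalization == "symmetric") (ha + hb) / 2 else sqrt(ha * hb)
  if (denom <= 0) return(0)
  min(I / denom, 1)
}

#' Pairwise HMI matrix
#'
#' @inheritParams jaccard_matrix
#' @inheritParams hmi
#' @return symmetric matrix of HMI values, unit diagonal for non-constant
#'   genes.
#' @export
hmi_matrix <- function(m, genes = m$gene_ids,
                       normalization = c("symmetric", "geometric")) {
  normalization <- match.arg(normalization)
  inc <- m$incidence[genes, , drop = FALSE]
  k <- nrow(inc)
  out <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k)) {
    out[i, i] <- hmi(inc[i, ], inc[i, ], normalization)
    if (i < k) for (j in (i + 1):k) {
      out[i, j] <- out[j, i] <- hmi(inc[i, ], inc[j, ], normalization)
    }
  }
  out
}

#' Build the HMI co-occurrence graph
#'
#' Nodes are genes; an edge joins u and v iff the distance `1 - HMI(u,v)`
#' is at most `threshold` (inclusive, "0.9 or less for a link"); edge weight
#' is the HMI itself.
#'
#' @param m an `occurrence_matrix`.
#' @param genes gene subset to include as nodes.
#' @param threshold maximum `1 - HMI` for a link, in (0,1\]; default 0.9.
#' @inheritParams hmi
#' @return an \pkg{igraph} graph with edge attribute `hmi` (also `weight`).
#' @export
build_hmi_graph <- function(m, genes = m$gene_ids, threshold = 0.9,
                            normalization = c("symmetric", "geometric")) {
  stopifnot(threshold > 0, threshold <= 1)
  H <- hmi_matrix(m, genes, normalization)
  adj <- (1 - H) <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  ends <- igraph::as_edgelist(g)
  w <- H[cbind(ends[, 1], ends[, 2])]
  igraph::E(g)$hmi <- w
  igraph::E(g)$weight <- w
  g$threshold <- threshold
  g
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest betweenness (recomputed after
#' each removal, on the unweighted topology), tracking the connected-
#' component partition after every removal, and returns the partition that
#' maximizes Newman modularity on the original graph. Modularity uses the
#' `weight` edge attribute (HMI) when present and `weighted = TRUE`.
#' Betweenness ties break on the lexicographically smallest (head, tail)
#' vertex-name pair, so the result is deterministic.
#'
#' @param graph an undirected \pkg{igraph} graph (possibly disconnected).
#' @param weighted use edge weights in the modularity computation
#'   (betweenness is always computed unweighted); default `TRUE`.
#' @return list with `membership` (named integer vector; isolated nodes are
#'   singleton communities), `modularity` of the returned partition, and
#'   `sizes` (community sizes).
#' @export
girvan_newman_communities <- function(graph, weighted = TRUE) {
  nv <- igraph::vcount(graph)
  if (nv == 0L)
    return(list(membership = integer(0), modularity = NA_real_,
                sizes = integer(0)))
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) {
    vnames <- as.character(seq_len(nv))
    igraph::V(graph)$name <- vnames
  }
  w0 <- if (weighted && !is.null(igraph::E(graph)$weight))
    igraph::E(graph)$weight else NULL
  part_of <- function(g) igraph::components(g)$membership
  score <- function(memb)
    igraph::modularity(graph, memb, weights = w0)
  g <- graph
  best_memb <- part_of(g)
  best_mod <- score(best_memb)
  while (igraph::ecount(g) > 0) {
    eb <- igraph::edge_betweenness(g, weights = NA)
    top <- which(eb == max(eb))
    if (length(top) > 1L) {
      ends <- igraph::as_edgelist(g)[top, , drop = FALSE]
      key <- apply(ends, 1L, function(r) paste(sort(r), collapse = "\r"))
      top <- top[order(key)][1L]
    }
    g <- igraph::delete_edges(g, top)
    memb <- part_of(g)
    mod <- score(memb)
    if (mod > best_mod + 1e-12) {
      best_mod <- mod
      best_memb <- memb
    }
  }
  memb <- setNames(as.integer(best_memb), vnames)
  list(membership = memb, modularity = best_mod,
       sizes = sort(table(memb), decreasing = TRUE))
}

#' Annotate a community partition with per-gene metadata
#'
#' Joins flags (e.g. pseudogene status, pathway dependence, publication
#' counts) onto the community table for export. Unknown genes in the
#' metadata produce a warning; duplicate metadata keys keep the last entry
#' with a warning.
#'
#' @param membership named community vector from
#'   [girvan_newman_communities()].
#' @param metadata data.frame with a `gene` column plus arbitrary flag or
#'   count columns; may be empty.
#' @return data.frame (gene, community, metadata columns).
#' @export
annotate_communities <- function(membership, metadata = NULL) {
  out <- data.frame(gene = names(membership),
                    community = as.integer(membership),
                    stringsAsFactors = FALSE)
  if (is.null(metadata) || nrow(metadata) == 0L) return(out)
  stopifnot("gene" %in% names(metadata))
  if (anyDuplicated(metadata$gene)) {
    warning("duplicate metadata keys; keeping last occurrence")
    metadata <- metadata[!duplicated(metadata$gene, fromLast = TRUE), ]
  }
  unknown <- setdiff(metadata$gene, out$gene)
  if (length(unknown))
    warning("metadata for genes not in partition: ",
            paste(head(unknown, 5), collapse = ", "))
  merged <- merge(out, metadata, by = "gene", all.x = TRUE, sort = FALSE)
  merged[match(out$gene, merged$gene), , drop = FALSE]
}

#' Write a community partition as TSV
#'
#' @param annotated data.frame from [annotate_communities()].
#' @param path output TSV path.
#' @export
write_communities <- function(annotated, path) {
  write.table(annotated, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
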