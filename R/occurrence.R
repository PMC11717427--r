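#' Build the genes x lists incidence matrix
#'
#' Joins a collection of gene lists into a binary incidence structure:
#' `incidence[g, i] = 1` iff gene g is a member of list i. Genes are rows
#' (sorted lexicographically), lists are columns in input order. Flagged-empty
#' lists are dropped; column sums recover the list sizes `T_i`.
#'
#' @param lists a list of [gene_list()] objects with unique `list_id`s,
#'   at least one non-empty.
#' @return an `occurrence_matrix`: list with `incidence` (integer matrix),
#'   `gene_ids`, `list_ids`, `T` (per-list sizes) and `n` (number of lists).
#' @export
build_occurrence_matrix <- function(lists) {
  lists <- Filter(function(l) inherits(l, "gene_list") && !l$empty, lists)
  if (length(lists) == 0L) stop("no non-empty gene lists supplied")
  ids <- vapply(lists, function(l) l$list_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate list_id: ", ids[duplicated(ids)][1])
  genes <- sort(unique(unlist(lapply(lists, function(l) l$genes))))
  inc <- matrix(0L, nrow = length(genes), ncol = length(lists),
                dimnames = list(genes, ids))
  for (i in seq_along(lists))
    inc[lists[[i]]$genes, i] <- 1L
  structure(list(incidence = inc, gene_ids = genes, list_ids = ids,
                 T = colSums(inc), n = length(lists)),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("<occurrence_matrix> %d genes x %d lists (T: %d-%d)\n",
              length(x$gene_ids), x$n, min(x$T), max(x$T)))
  invisible(x)
}

#' Most frequently listed genes
#'
#' The top `g` genes occurring in the greatest numbers of lists, sorted by
#' frequency descending with lexicographic tie-break on gene id, so the
#' culling is deterministic.
#'
#' @param m an `occurrence_matrix`.
#' @param g number of genes to cull, `1 <= g <=` gene count.
#' @return character vector of `g` gene ids, in rank order.
#' @export
top_genes <- function(m, g) {
  stopifnot(inherits(m, "occurrence_matrix"))
  freq <- rowSums(m$incidence)
  if (g < 1 || g > length(freq))
    stop("g must be between 1 and the number of genes (", length(freq), ")")
  ord <- order(-freq, names(freq))  # gene_ids are pre-sorted rownames
  names(freq)[ord][seq_len(g)]
}

#' Selectivity-weighted regulation score of a gene set
#'
#' For a chosen set of genes, sums over all n lists the fraction
#' `S_i / T_i`, where `S_i` is the overlap of the set with list i and `T_i`
#' the list size. Small, selective lists that hit the set contribute more
#' than large, unselective ones.
#'
#' @param m an `occurrence_matrix`.
#' @param geneset character vector of gene ids, a subset of the matrix genes.
#' @return a single nonnegative number; equals `n` when `geneset` is the
#'   whole gene universe of `m`.
#' @export
rg_set_score <- function(m, geneset) {
  stopifnot(inherits(m, "occurrence_matrix"))
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0L) return(0)
  missing <- setdiff(geneset, m$gene_ids)
  if (length(missing))
    stop("genes not in matrix: ", paste(head(missing, 5), collapse = ", "))
  S <- colSums(m$incidence[geneset, , drop = FALSE])
  sum(S / m$T)
}

#' Per-gene regulation scores over the top-g set
#'
#' Culls the top `g` genes by frequency, then scores each member j as the
#' sum over lists containing j of `S_i / T_i`, where `S_i` is the overlap of
#' the full top-g set with list i: each list votes for its members with its
#' selectivity-weighted overlap. The alternative pure-selectivity score
#' (`sum of 1/T_i` over lists containing j, ignoring the rest of the set) is
#' available via `method = "selectivity"`.
#'
#' @param m an `occurrence_matrix`.
#' @param g size of the culled top set.
#' @param method `"set-weighted"` (default) or `"selectivity"`.
#' @return data.frame (gene, frequency, r_score, rank) sorted by `r_score`
#'   descending, lexicographic tie-break; attribute `"contributions"` holds
#'   the per-gene list of `S_i/T_i` terms for auditing.
#' @export
rg_gene_scores <- function(m, g, method = c("set-weighted", "selectivity")) {
  method <- match.arg(method)
  G <- top_genes(m, g)
  sub <- m$incidence[G, , drop = FALSE]
  S <- colSums(sub)
  w <- if (method == "set-weighted") S / m$T else 1 / m$T
  r <- as.numeric(sub %*% w)
  freq <- rowSums(sub)
  ord <- order(-r, G)
  out <- data.frame(gene = G[ord], frequency = as.integer(freq[ord]),
                    r_score = r[ord], rank = seq_along(G),
                    stringsAsFactors = FALSE)
  attr(out, "contributions") <- lapply(setNames(seq_along(G), G), function(j) {
    on <- sub[j, ] == 1L
    setNames(w[on], m$list_ids[on])
  })[out$gene]
  out
}

#' Stability of the prioritized set to the choice of g
#'
#' Measures how many of the top `g1` genes ranked under the g1-set score
#' remain in the top `g1` when ranked under the (larger) g2-set score.
#'
#' @param m an `occurrence_matrix`.
#' @param g1,g2 set sizes with `g1 <= g2 <=` gene count.
#' @return integer overlap in `[0, g1]`.
#' @export
rank_stability <- function(m, g1, g2) {
  stopifnot(g1 <= g2)
  a <- rg_gene_scores(m, g1)$gene
  b <- head(rg_gene_scores(m, g2)$gene, g1)
  length(intersect(a, b))
}

#' Write a ranked-gene table with its score audit
#'
#' @param scores result of [rg_gene_scores()].
#' @param path output TSV path.
#' @param audit optional JSON path for the per-gene `S_i/T_i` contributions.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path, audit = NULL) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(audit)) {
    contrib <- attr(scores, "contributions")
    jsonlite::write_json(lapply(contrib, as.list), audit,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
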