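#' Inter-chain residue pairs constrained by PAE and distance
#'
#' A pair (i in bait, j in prey) is constrained iff the Calpha-Calpha
#' distance is strictly below `dist_max` and the symmetric maximum of the
#' two PAE entries, `max(PAE[i,j], PAE[j,i])`, is strictly below `pae_max`.
#' An all-atom minimum-distance mode is available for sensitivity analysis.
#'
#' @param model a `dimer_model` from [load_dimer_model()].
#' @param pae_max maximum PAE in Angstrom (default 5, strict `<`).
#' @param dist_max maximum distance in Angstrom (default 6, strict `<`).
#' @param distance `"ca"` (Calpha-Calpha, default) or `"all-atom"`
#'   (minimum inter-atomic distance per residue pair).
#' @return data.frame (res_bait, res_prey, ca_distance, pae_ab, pae_ba),
#'   residue indices 1-based per chain; zero rows when nothing passes.
#' @export
constrained_pairs <- function(model, pae_max = 5, dist_max = 6,
                              distance = c("ca", "all-atom")) {
  distance <- match.arg(distance)
  la <- nchar(model$bait$sequence)
  lb <- nchar(model$prey$sequence)
  if (distance == "ca") {
    A <- model$bait$ca
    B <- model$prey$ca
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    D <- sqrt(pmax(d2, 0))
  } else {
    D <- matrix(Inf, la, lb)
    aa <- model$bait$atoms; ab <- model$prey$atoms
    ia <- match(aa$resno, model$bait$resno)
    ib <- match(ab$resno, model$prey$resno)
    XA <- as.matrix(aa[, c("x", "y", "z")])
    XB <- as.matrix(ab[, c("x", "y", "z")])
    dd <- sqrt(pmax(outer(rowSums(XA^2), rowSums(XB^2), "+") -
                      2 * tcrossprod(XA, XB), 0))
    for (k in seq_len(nrow(aa)))
      D[ia[k], ] <- pmin(D[ia[k], ], tapply(dd[k, ], ib, min)[as.character(seq_len(lb))])
  }
  pab <- model$pae[seq_len(la), la + seq_len(lb), drop = FALSE]
  pba <- t(model$pae[la + seq_len(lb), seq_len(la), drop = FALSE])
  hit <- which(D < dist_max & pmax(pab, pba) < pae_max, arr.ind = TRUE)
  out <- data.frame(res_bait = as.integer(hit[, 1]),
                    res_prey = as.integer(hit[, 2]),
                    ca_distance = D[hit],
                    pae_ab = pab[hit], pae_ba = pba[hit])
  out <- out[order(out$res_bait, out$res_prey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call an interaction from a triaged dimer model
#'
#' Applies both generations of significance criteria to the constrained
#' pair set. The first-generation verdict (`passes_v1`) requires a ranking
#' score strictly above `min_rank` and at least `min_prey_residues` distinct
#' constrained residues in the prey (candidate) chain. The revised verdict
#' (`passes_v2`) requires the same ranking bound and a product
#' `n_bait * n_prey` strictly above `min_product`.
#'
#' @param model a `dimer_model`.
#' @param pairs optional precomputed [constrained_pairs()] result; computed
#'   with defaults when missing.
#' @param min_rank ranking-score threshold (default 0.6, strict `>`).
#' @param min_prey_residues minimum distinct prey residues (default 20,
#'   inclusive `>=`).
#' @param min_product n_bait x n_prey threshold (default 100, strict `>`).
#' @inheritParams constrained_pairs
#' @return an `interaction_call`: list with the pair table, `n_bait`,
#'   `n_prey`, `ranking`, `passes_v1`, `passes_v2` and the thresholds used.
#' @export
call_interaction <- function(model, pairs = NULL, min_rank = 0.6,
                             min_prey_residues = 20, min_product = 100,
                             pae_max = 5, dist_max = 6) {
  if (is.null(pairs)) pairs <- constrained_pairs(model, pae_max, dist_max)
  ranking <- ranking_score(model$score)
  n_bait <- length(unique(pairs$res_bait))
  n_prey <- length(unique(pairs$res_prey))
  structure(
    list(pair_id = c(bait = model$bait$chain_id, prey = model$prey$chain_id),
         pairs = pairs, n_bait = n_bait, n_prey = n_prey,
         ranking = ranking,
         passes_v1 = ranking > min_rank && n_prey >= min_prey_residues,
         passes_v2 = ranking > min_rank && n_bait * n_prey > min_product,
         thresholds = list(min_rank = min_rank,
                           min_prey_residues = min_prey_residues,
                           min_product = min_product,
                           pae_max = pae_max, dist_max = dist_max)),
    class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf(
    "<interaction_call> %s-%s: %d pairs (n_bait %d x n_prey %d), ranking %.3f, v1 %s, v2 %s\n",
    x$pair_id["bait"], x$pair_id["prey"], nrow(x$pairs), x$n_bait, x$n_prey,
    x$ranking, x$passes_v1, x$passes_v2))
  invisible(x)
}

#' Per-residue constrained-position profile
#'
#' Marks, for each chain, the residue positions participating in at least
#' one constrained pair — the linear footprint of the predicted interface.
#'
#' @param model a `dimer_model`.
#' @inheritParams call_interaction
#' @param path optional TSV output (chain, position, constrained).
#' @return list of two logical vectors, `bait` and `prey`, one element per
#'   residue.
#' @export
constrained_profile <- function(model, pairs = NULL, pae_max = 5,
                                dist_max = 6, path = NULL) {
  if (is.null(pairs)) pairs <- constrained_pairs(model, pae_max, dist_max)
  bait <- seq_len(nchar(model$bait$sequence)) %in% pairs$res_bait
  prey <- seq_len(nchar(model$prey$sequence)) %in% pairs$res_prey
  if (!is.null(path)) {
    tab <- rbind(
      data.frame(chain = model$bait$chain_id, position = seq_along(bait),
                 constrained = bait),
      data.frame(chain = model$prey$chain_id, position = seq_along(prey),
                 constrained = prey))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(bait = bait, prey = prey)
}

kabsch <- function(P, Q) {
  # optimal rotation mapping P onto Q (n x 3 each), plus translation
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
  s <- svd(H)
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq)
}

#' RMSD between two models after anchor-chain superposition
#'
#' Rigidly superposes `model_alt` onto `model_ref` by least squares (Kabsch)
#' over the Calpha atoms of the anchor chain, then reports the RMSD over
#' the Calpha atoms of the other (mobile-partner) chain. Whole-complex RMSD
#' over all Calpha atoms is available with `scope = "complex"`.
#'
#' @param model_ref,model_alt `dimer_model`s sharing both chain sequences.
#' @param anchor_chain `"bait"` or `"prey"`: chain used for the alignment.
#' @param scope `"partner"` (default) or `"complex"`.
#' @return RMSD in Angstrom.
#' @export
superpose_rmsd <- function(model_ref, model_alt,
                           anchor_chain = c("bait", "prey"),
                           scope = c("partner", "complex")) {
  anchor_chain <- match.arg(anchor_chain)
  scope <- match.arg(scope)
  if (model_ref$bait$sequence != model_alt$bait$sequence ||
      model_ref$prey$sequence != model_alt$prey$sequence)
    stop("models differ in chain sequences")
  other <- if (anchor_chain == "bait") "prey" else "bait"
  fit <- kabsch(model_alt[[anchor_chain]]$ca, model_ref[[anchor_chain]]$ca)
  transform <- function(X)
    sweep(sweep(X, 2, fit$cp) %*% t(fit$R), 2, fit$cq, "+")
  mob <- if (scope == "partner") {
    list(transform(model_alt[[other]]$ca))
  } else {
    list(transform(model_alt$bait$ca), transform(model_alt$prey$ca))
  }
  ref <- if (scope == "partner") list(model_ref[[other]]$ca)
         else list(model_ref$bait$ca, model_ref$prey$ca)
  dev2 <- mapply(function(a, b) rowSums((a - b)^2), mob, ref,
                 SIMPLIFY = FALSE)
  sqrt(mean(unlist(dev2)))
}

#' Convergence of a ranked model ensemble
#'
#' Superposes every model of an ensemble onto the highest-ranking one and
#' tabulates ranking score against RMSD, sorted by RMSD ascending — tightly
#' clustered high-scoring models indicate a converged prediction.
#'
#' @param models list of `dimer_model`s (>= 1) of the same protein pair.
#' @inheritParams superpose_rmsd
#' @return data.frame (model, ranking, rmsd) with the top model first at
#'   RMSD 0.
#' @export
convergence_table <- function(models, anchor_chain = c("bait", "prey")) {
  anchor_chain <- match.arg(anchor_chain)
  stopifnot(length(models) >= 1)
  rk <- vapply(models, function(m) ranking_score(m$score), numeric(1))
  top <- which.max(rk)
  rmsd <- vapply(seq_along(models), function(i)
    superpose_rmsd(models[[top]], models[[i]], anchor_chain), numeric(1))
  nm <- names(models)
  if (is.null(nm)) nm <- sprintf("model%02d", seq_along(models))
  out <- data.frame(model = nm, ranking = rk, rmsd = rmsd,
                    stringsAsFactors = FALSE)
  out[order(out$rmsd, -out$ranking), , drop = FALSE]
}

#' Concordance of two interaction calls for the same pair
#'
#' Compares calls made for one protein pair by two prediction pipelines
#' (e.g. successive predictor versions). When both calls pass, the verdict
#' is `similar_interface` iff the Jaccard overlap of the constrained
#' prey-residue sets reaches `overlap_min` (inclusive), else
#' `different_interface`; when exactly one passes, `one_sided`; otherwise
#' `neither`.
#'
#' @param call_a,call_b `interaction_call`s for the same pair.
#' @param overlap_min minimum Jaccard overlap for "similar" (default 0.25;
#'   this cutoff is a package choice, reported with the verdict).
#' @param criteria which verdict flag decides "passes": `"v1"` or `"v2"`.
#' @return list with `verdict` (factor of the four outcomes), `overlap`
#'   (Jaccard index, `NA` unless both pass) and `overlap_min`.
#' @export
interface_concordance <- function(call_a, call_b, overlap_min = 0.25,
                                  criteria = c("v1", "v2")) {
  criteria <- match.arg(criteria)
  pass <- function(cl) if (criteria == "v1") cl$passes_v1 else cl$passes_v2
  pa <- pass(call_a); pb <- pass(call_b)
  overlap <- NA_real_
  verdict <- if (pa && pb) {
    sa <- unique(call_a$pairs$res_prey)
    sb <- unique(call_b$pairs$res_prey)
    overlap <- length(intersect(sa, sb)) / length(union(sa, sb))
    if (overlap >= overlap_min) "similar_interface" else "different_interface"
  } else if (pa || pb) "one_sided" else "neither"
  list(verdict = verdict, overlap = overlap, overlap_min = overlap_min)
}

#' Export interaction calls as a network
#'
#' Builds the regulator-candidate interaction network: nodes are proteins
#' with a `role` attribute, edges carry the ranking score, normalized
#' interface area, both verdict flags, cross-version concordance and an
#' experimental-support flag. Written as GraphML plus an edge-list TSV.
#'
#' @param calls list of `interaction_call`s, at most one per protein pair.
#' @param area_norm optional numeric vector of normalized interface areas,
#'   one per call.
#' @param concordance optional character vector of concordance verdicts.
#' @param support optional logical vector flagging experimental support.
#' @param graphml,tsv optional output paths.
#' @return the \pkg{igraph} graph, invisibly when files are written.
#' @export
export_network <- function(calls, area_norm = NULL, concordance = NULL,
                           support = NULL, graphml = NULL, tsv = NULL) {
  key <- vapply(calls, function(cl)
    paste(cl$pair_id["bait"], cl$pair_id["prey"], sep = "|"), character(1))
  if (anyDuplicated(key))
    stop("duplicate pair entries: ", key[duplicated(key)][1])
  if (length(calls) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
    if (!is.null(tsv))
      write.table(data.frame(from = character(0), to = character(0)), tsv,
                  sep = "\t", quote = FALSE, row.names = FALSE)
    return(if (is.null(graphml) && is.null(tsv)) g else invisible(g))
  }
  edges <- data.frame(
    from = vapply(calls, function(cl) unname(cl$pair_id["bait"]), character(1)),
    to = vapply(calls, function(cl) unname(cl$pair_id["prey"]), character(1)),
    ranking = vapply(calls, function(cl) cl$ranking, numeric(1)),
    n_bait = vapply(calls, function(cl) cl$n_bait, integer(1)),
    n_prey = vapply(calls, function(cl) cl$n_prey, integer(1)),
    passes_v1 = vapply(calls, function(cl) cl$passes_v1, logical(1)),
    passes_v2 = vapply(calls, function(cl) cl$passes_v2, logical(1)),
    stringsAsFactors = FALSE)
  edges$area_norm <- if (is.null(area_norm)) NA_real_ else area_norm
  edges$concordance <- if (is.null(concordance)) NA_character_ else concordance
  edges$support <- if (is.null(support)) FALSE else support
  nodes <- data.frame(
    name = unique(c(edges$from, edges$to)), stringsAsFactors = FALSE)
  nodes$role <- ifelse(nodes$name %in% edges$from, "regulator", "candidate")
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(tsv))
    write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (is.null(graphml) && is.null(tsv)) g else invisible(g)
}
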