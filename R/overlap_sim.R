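#' Exact probability that a random list overlaps a top gene set
#'
#' For a universe of `N` genes, a fixed top set of `g` genes, and a list of
#' `T` genes drawn uniformly without replacement, the probability of at
#' least one overlap is `1 - C(N-g, T) / C(N, T)`, evaluated with
#' log-binomials so it is stable at genome scale (N = 20,000).
#'
#' @param N genome size (positive integer).
#' @param g top-set size, `0 <= g <= N`.
#' @param T_ list size, `1 <= T_ <= N`.
#' @return probability in \[0,1\]; 0 when `g = 0`, 1 when `T_ > N - g`.
#' @export
p_overlap_analytic <- function(N, g, T_) {
  if (N < 1 || g < 0 || g > N || T_ < 1 || T_ > N)
    stop("require 1 <= T_ <= N and 0 <= g <= N")
  if (g == 0) return(0)
  if (T_ > N - g) return(1)
  1 - exp(lchoose(N - g, T_) - lchoose(N, T_))
}

#' Monte-Carlo distribution of the overlap probability
#'
#' Emulates the box-plot simulation: each of `runs` runs draws
#' `lists_per_run` lists of size `T_` uniformly from the `N`-gene universe
#' and records the fraction that share at least one gene with a fixed
#' `g`-gene top set. The per-list overlap count of a uniform `T_`-subset
#' with a fixed `g`-set is hypergeometric, so draws use
#' `rhyper(m = g, n = N - g, k = T_)` directly.
#'
#' @inheritParams p_overlap_analytic
#' @param runs number of independent runs (default 100).
#' @param lists_per_run lists drawn per run (default 398, the corpus size
#'   the simulation mirrors).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list with `estimates` (length `runs`, each in \[0,1\]),
#'   `summary` (quartiles) and the parameters.
#' @export
simulate_overlap <- function(N, g, T_, runs = 100, lists_per_run = 398,
                             seed = 1) {
  stopifnot(runs >= 1, lists_per_run >= 1)
  if (g < 0 || g > N || T_ < 1 || T_ > N) stop("parameters out of range")
  set.seed(seed)
  est <- vapply(seq_len(runs), function(r) {
    S <- rhyper(lists_per_run, m = g, n = N - g, k = T_)
    mean(S > 0)
  }, numeric(1))
  list(N = N, g = g, T_ = T_, runs = runs, lists_per_run = lists_per_run,
       seed = seed, estimates = est,
       summary = stats::quantile(est, c(0, 0.25, 0.5, 0.75, 1)))
}

#' Tidy table of overlap simulations over a parameter grid
#'
#' @param grid data.frame with columns `N`, `g`, `T_`.
#' @inheritParams simulate_overlap
#' @return data.frame (N, g, T_, run, estimate), ready for box plots.
#' @export
simulate_overlap_grid <- function(grid, runs = 100, lists_per_run = 398,
                                  seed = 1) {
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    sim <- simulate_overlap(grid$N[i], grid$g[i], grid$T_[i], runs,
                            lists_per_run, seed + i - 1L)
    data.frame(N = grid$N[i], g = grid$g[i], T_ = grid$T_[i],
               run = seq_len(runs), estimate = sim$estimates)
  }))
}

#' Grow gene lists by preferential attachment
#'
#' Generates `n_lists` lists sequentially from an `N`-gene universe: each
#' list samples its genes without replacement with probability proportional
#' to `(occurrences so far) + attachment_strength`. Small strength gives
#' rich-get-richer dynamics; as strength grows the process approaches
#' uniform sampling. With `attachment_strength = 0`, genes with zero
#' occurrences can never be drawn, so initial counts must make the weights
#' non-degenerate (see `init_counts`).
#'
#' @param N universe size.
#' @param n_lists number of lists to generate.
#' @param list_size_sampler function(i) returning the size of list i
#'   (each `<= N`); default: fixed size 10.
#' @param attachment_strength nonnegative smoothing constant.
#' @param seed integer seed.
#' @param init_counts optional starting occurrence counts (length `N`).
#' @return list with `lists` (a collection of [gene_list()]), `matrix`
#'   (the [build_occurrence_matrix()] of the collection) and `counts`
#'   (final per-gene occurrence counts, named).
#' @export
preferential_attachment_lists <- function(N, n_lists,
                                          list_size_sampler = function(i) 10L,
                                          attachment_strength = 1,
                                          seed = 1,
                                          init_counts = NULL) {
  stopifnot(attachment_strength >= 0, N >= 1, n_lists >= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(N))
  counts <- if (is.null(init_counts)) rep(0, N) else as.numeric(init_counts)
  stopifnot(length(counts) == N)
  lists <- vector("list", n_lists)
  for (i in seq_len(n_lists)) {
    sz <- as.integer(list_size_sampler(i))
    if (sz > N) stop("list size ", sz, " exceeds universe size ", N)
    w <- counts + attachment_strength
    if (sum(w > 0) < sz)
      stop("too few genes with positive weight to fill a list of ", sz)
    pick <- sample.int(N, sz, prob = w)
    counts[pick] <- counts[pick] + 1
    lists[[i]] <- gene_list(sprintf("pa%04d", i), genes[pick])
  }
  list(lists = lists, matrix = build_occurrence_matrix(lists),
       counts = setNames(counts, genes))
}
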