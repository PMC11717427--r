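# shared in-code fixtures

toy_matrix <- function() {
  # the worked 3-list example: L1={a,b}, L2={a,c}, L3={a,b,c,d}
  build_occurrence_matrix(list(
    gene_list("L1", c("a", "b")),
    gene_list("L2", c("a", "c")),
    gene_list("L3", c("a", "b", "c", "d"))))
}

random_corpus <- function(n_genes, n_lists, seed) {
  set.seed(seed)
  lists <- lapply(seq_len(n_lists), function(i) {
    sz <- sample(2:max(3, n_genes %/% 2), 1)
    gene_list(sprintf("L%03d", i),
              sample(sprintf("g%03d", seq_len(n_genes)), sz))
  })
  build_occurrence_matrix(lists)
}

# brute-force r_g scorer: explicit double loop over genes and lists
brute_rg_scores <- function(m, G) {
  S <- sapply(seq_len(m$n), function(i)
    sum(G %in% m$gene_ids[m$incidence[, i] == 1L]))
  setNames(vapply(G, function(j) {
    tot <- 0
    for (i in seq_len(m$n))
      if (m$incidence[j, i] == 1L) tot <- tot + unname(S[i] / m$T[i])
    tot
  }, numeric(1), USE.NAMES = FALSE), G)
}

# brute-force HMI from the explicit 2x2 table
brute_hmi <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1); n10 <- sum(a == 1 & b == 0)
  n01 <- sum(a == 0 & b == 1); n00 <- sum(a == 0 & b == 0)
  pj <- c(n00, n01, n10, n11) / n
  pa <- c(n00 + n01, n10 + n11) / n
  pb <- c(n00 + n10, n01 + n11) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pxa <- c(pa[1], pa[1], pa[2], pa[2])
  pxb <- c(pb[1], pb[2], pb[1], pb[2])
  I <- 0
  for (k in 1:4)
    if (pj[k] > 0) I <- I + pj[k] * log(pj[k] / (pxa[k] * pxb[k]))
  denom <- h(pa) + h(pb)
  if (denom <= 0) 0 else min(2 * I / denom, 1)
}

# brute-force constrained-pair oracle: plain double loop
brute_pairs <- function(model, pae_max = 5, dist_max = 6) {
  la <- nchar(model$bait$sequence); lb <- nchar(model$prey$sequence)
  out <- list()
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    d <- sqrt(sum((model$bait$ca[i, ] - model$prey$ca[j, ])^2))
    mp <- max(model$pae[i, la + j], model$pae[la + j, i])
    if (d < dist_max && mp < pae_max)
      out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L)
    return(data.frame(res_bait = integer(0), res_prey = integer(0)))
  m <- do.call(rbind, out)
  data.frame(res_bait = as.integer(m[, 1]), res_prey = as.integer(m[, 2]))
}

# brute-force longest codon-run oracle: enumerate every run in every frame
brute_six_frame <- function(seq) {
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  stops <- c("TAA", "TAG", "TGA")
  best_per_frame <- sapply(c(1, 2, 3, -1, -2, -3), function(fr) {
    s <- if (fr > 0) seq else revcomp(seq)
    off <- abs(fr) - 1
    ncod <- (nchar(s) - off) %/% 3
    if (ncod == 0) return(0L)
    cods <- substring(s, off + 3 * seq_len(ncod) - 2, off + 3 * seq_len(ncod))
    is_stop <- cods %in% stops
    best <- 0L; cur <- 0L
    for (k in seq_len(ncod)) {
      cur <- if (is_stop[k]) 0L else cur + 1L
      best <- max(best, cur)
    }
    best
  })
  setNames(best_per_frame, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

make_translated_copy <- function(model, angles = c(0.3, -0.5, 1.1),
                                 shift = c(1, -2, 3)) {
  # apply one rigid transform to both chains
  Rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, byrow = TRUE)
  Ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, byrow = TRUE)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rx(angles[1]) %*% Ry(angles[2]) %*% Rz(angles[3])
  out <- model
  for (ch in c("bait", "prey")) {
    out[[ch]]$ca <- sweep(model[[ch]]$ca %*% t(R), 2, shift, "+")
    xyz <- as.matrix(model[[ch]]$atoms[, c("x", "y", "z")])
    out[[ch]]$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, shift, "+")
  }
  out
}

load_fixture <- function(fx) {
  load_dimer_model(fx$paths$coords, fx$paths$pae, fx$paths$scores)
}
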