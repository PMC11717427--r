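#' Generate a synthetic corpus of gene lists with planted structure
#'
#' Emulates a meta-analysis corpus: `n_lists` lists of widely varying sizes
#' drawn from an `n_genes` universe, with (a) planted blocks of genes that
#' co-occur in designated lists with a stated probability, and (b) optional
#' "hub" genes included in any list with an elevated rate, mimicking
#' frequently perturbed genes. All remaining slots are filled uniformly at
#' random (the background occurrence process). List sizes default to a
#' log-uniform draw over 10-2,000 genes, mirroring the heterogeneity of
#' published tables.
#'
#' @param n_genes universe size (default 20000).
#' @param n_lists number of lists (default 398).
#' @param size_range 2-vector, log-uniform list-size range; sizes are
#'   capped at `n_genes`.
#' @param blocks list of planted blocks, each a list with `size` (genes in
#'   the block), `p` (co-occurrence probability per designated list) and
#'   `n_lists` (how many lists carry the block).
#' @param n_hubs,hub_rate number of hub genes and their per-list inclusion
#'   probability.
#' @param seed integer seed; same seed, same corpus.
#' @param ground_truth optional JSON sidecar path for the planted structure.
#' @return list with `lists` (a [gene_list()] collection) and `truth`
#'   (block members, designated lists, hub genes).
#' @export
gen_list_corpus <- function(n_genes = 20000, n_lists = 398,
                            size_range = c(10, 2000), blocks = list(),
                            n_hubs = 0, hub_rate = 0.5, seed = 1,
                            ground_truth = NULL) {
  stopifnot(n_genes >= 1, n_lists >= 1, size_range[1] >= 1)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  sizes <- pmin(round(exp(runif(n_lists, log(size_range[1]),
                                log(min(size_range[2], n_genes))))), n_genes)
  for (b in blocks)
    if (b$size > max(sizes))
      stop("planted block of ", b$size,
           " genes exceeds the largest list size ", max(sizes))
  # assign disjoint gene index ranges: blocks first, then hubs
  cursor <- 0L
  truth_blocks <- list()
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    idx <- cursor + seq_len(b$size)
    cursor <- cursor + b$size
    truth_blocks[[k]] <- list(
      genes = genes[idx], p = b$p,
      lists = sort(sample.int(n_lists, min(b$n_lists, n_lists))))
  }
  hub_idx <- if (n_hubs > 0) cursor + seq_len(n_hubs) else integer(0)
  hubs <- genes[hub_idx]
  cursor <- cursor + n_hubs
  if (cursor > n_genes) stop("blocks and hubs exceed the gene universe")
  lists <- vector("list", n_lists)
  for (i in seq_len(n_lists)) {
    members <- character(0)
    for (b in truth_blocks)
      if (i %in% b$lists)
        members <- c(members, b$genes[runif(length(b$genes)) < b$p])
    if (n_hubs > 0)
      members <- c(members, hubs[runif(n_hubs) < hub_rate])
    need <- sizes[i] - length(members)
    if (need > 0) {
      pool <- setdiff(genes, members)
      members <- c(members, sample(pool, min(need, length(pool))))
    }
    lists[[i]] <- gene_list(sprintf("list%04d", i), members,
                            category = "mRNA")
  }
  truth <- list(blocks = truth_blocks, hubs = hubs, sizes = sizes,
                seed = seed)
  if (!is.null(ground_truth))
    jsonlite::write_json(truth, ground_truth, auto_unbox = TRUE)
  list(lists = lists, truth = truth)
}

spread_indices <- function(n, k) {
  # k well-separated 1-based indices within 1..n
  unique(round(seq(1, n, length.out = k)))
}

#' Generate an on-disk synthetic dimer fixture with planted contacts
#'
#' Writes a loadable two-chain model (PDB), a PAE matrix (JSON) and score
#' metadata (JSON) such that [constrained_pairs()] at default thresholds
#' recovers exactly the planted pair set. Chains are idealized Calpha
#' traces with 3.8 A consecutive spacing along separated straight lines;
#' each planted prey residue is relocated onto a 5 A arc around its bait
#' partner (several prey can share one bait), the PAE carries signal below
#' threshold on planted pairs and noise above it everywhere else, and a
#' generation-time self-check re-measures every planted distance. One
#' carbon sphere per residue stands in for the side chain in SASA
#' computations.
#'
#' @param len_bait,len_prey chain lengths (residues).
#' @param n_bait,n_prey distinct constrained residues to plant per chain;
#'   the planted pair set pairs them so both counts are met (requires
#'   `max/min <= 8`, the capacity of a 5 A contact arc). Use
#'   `n_bait = n_prey = 0` for a non-interacting fixture.
#' @param contact_distance planted pair Calpha distance (default 5, must
#'   be < 6).
#' @param separation bulk inter-chain spacing (default 20, must be >= 12).
#' @param pae_signal,pae_noise PAE on planted pairs (< 5) and elsewhere
#'   across chains (>= 8).
#' @param iptm,ptm,disorder_frac,version score metadata (see
#'   [model_score()]).
#' @param seed integer seed (sequences and arc phases).
#' @param outdir output directory; created if missing.
#' @param prefix file-name prefix.
#' @return list with file `paths` (coords, pae, scores, truth) and `truth`
#'   (the planted pair table and expected counts).
#' @export
gen_dimer_fixture <- function(len_bait = 60, len_prey = 50,
                              n_bait = 10, n_prey = 10,
                              contact_distance = 5, separation = 20,
                              pae_signal = 3, pae_noise = 20,
                              iptm = 0.8, ptm = 0.7, disorder_frac = NULL,
                              version = "AF2-like", seed = 1,
                              outdir = tempdir(), prefix = "dimer") {
  stopifnot(contact_distance < 6, separation >= 12,
            pae_signal < 5, pae_noise >= 8,
            n_bait <= len_bait, n_prey <= len_prey)
  if (xor(n_bait == 0, n_prey == 0))
    stop("n_bait and n_prey must both be zero or both positive")
  if (n_bait > 0 && max(n_bait, n_prey) > 8 * min(n_bait, n_prey))
    stop("geometric construction failure: a 5 A contact arc holds at most ",
         "8 partners per residue (need ", max(n_bait, n_prey), " on ",
         min(n_bait, n_prey), ")")
  set.seed(seed)
  aa <- setdiff(names(AA1TO3), "X")
  seq_a <- sample(aa, len_bait, replace = TRUE)
  seq_b <- sample(aa, len_prey, replace = TRUE)
  # idealized helical Calpha traces (3.8 A consecutive spacing, rise 1.42,
  # radius 2.3, ~100 deg/residue) so superposition anchors are never
  # collinear; helix axes run along x, separated in y
  helix <- function(n, y0) {
    i <- seq_len(n) - 1
    omega <- 100 * pi / 180
    cbind(1.42 * i, y0 + 2.3 * cos(omega * i), 2.3 * sin(omega * i))
  }
  ca_a <- helix(len_bait, 0)
  ca_b <- helix(len_prey, separation)
  pairs <- data.frame(res_bait = integer(0), res_prey = integer(0))
  if (n_bait > 0) {
    bait_idx <- spread_indices(len_bait, n_bait)
    prey_idx <- spread_indices(len_prey, n_prey)
    n_bait <- length(bait_idx); n_prey <- length(prey_idx)
    if (n_prey >= n_bait) {
      owner <- bait_idx[ceiling(seq_len(n_prey) * n_bait / n_prey)]
      pairs <- data.frame(res_bait = owner, res_prey = prey_idx)
      anchor <- ca_a; anchored <- "res_bait"; moved <- "res_prey"
      move_ca <- function(j, xyz) ca_b[j, ] <<- xyz
    } else {
      owner <- prey_idx[ceiling(seq_len(n_bait) * n_prey / n_bait)]
      pairs <- data.frame(res_bait = bait_idx, res_prey = owner)
      anchor <- ca_b; anchored <- "res_prey"; moved <- "res_bait"
      move_ca <- function(j, xyz) ca_a[j, ] <<- xyz
    }
    # the more numerous side's contact residues fan out on a circle of
    # radius contact_distance around their partner, normal to the helix axis
    phase <- runif(1, 0, 2 * pi)
    for (b in unique(pairs[[anchored]])) {
      js <- pairs[[moved]][pairs[[anchored]] == b]
      ang <- phase + 2 * pi * (seq_along(js) - 1) / 8
      for (t in seq_along(js))
        move_ca(js[t], anchor[b, ] + contact_distance * c(0, cos(ang[t]),
                                                          sin(ang[t])))
    }
    d <- sqrt(rowSums((ca_a[pairs$res_bait, , drop = FALSE] -
                         ca_b[pairs$res_prey, , drop = FALSE])^2))
    if (any(abs(d - contact_distance) > 1e-6))
      stop("geometric construction failure: planted distance check failed")
    pairs$res_bait <- as.integer(pairs$res_bait)
    pairs$res_prey <- as.integer(pairs$res_prey)
    pairs <- pairs[order(pairs$res_bait, pairs$res_prey), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  L <- len_bait + len_prey
  pae <- matrix(pae_noise, L, L)
  pae[seq_len(len_bait), seq_len(len_bait)] <- 2
  pae[len_bait + seq_len(len_prey), len_bait + seq_len(len_prey)] <- 2
  diag(pae) <- 0
  if (nrow(pairs)) {
    pae[cbind(pairs$res_bait, len_bait + pairs$res_prey)] <- pae_signal
    pae[cbind(len_bait + pairs$res_prey, pairs$res_bait)] <- pae_signal
  }
  plddt_a <- ifelse(seq_len(len_bait) %in% pairs$res_bait, 90, 70)
  plddt_b <- ifelse(seq_len(len_prey) %in% pairs$res_prey, 90, 70)
  mk_atoms <- function(chain, seq1, ca, plddt)
    data.frame(atom = "CA", resname = AA1TO3[seq1], chain = chain,
               resno = seq_len(nrow(ca)), x = ca[, 1], y = ca[, 2],
               z = ca[, 3], b = plddt, element = "C",
               stringsAsFactors = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(coords = file.path(outdir, paste0(prefix, ".pdb")),
                pae = file.path(outdir, paste0(prefix, "_pae.json")),
                scores = file.path(outdir, paste0(prefix, "_scores.json")),
                truth = file.path(outdir, paste0(prefix, "_truth.json")))
  write_pdb(list(list(atoms = mk_atoms("A", seq_a, ca_a, plddt_a)),
                 list(atoms = mk_atoms("B", seq_b, ca_b, plddt_b))),
            paths$coords)
  jsonlite::write_json(list(pae = pae), paths$pae, digits = NA,
                       matrix = "rowmajor")
  sc <- list(iptm = iptm, ptm = ptm, version = version)
  if (!is.null(disorder_frac)) sc$disorder_frac <- disorder_frac
  jsonlite::write_json(sc, paths$scores, auto_unbox = TRUE, digits = NA)
  truth <- list(pairs = pairs,
                n_bait = length(unique(pairs$res_bait)),
                n_prey = length(unique(pairs$res_prey)),
                contact_distance = contact_distance, seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, truth = truth)
}

STOP_CASSETTE_FWD <- "TAAATAAATAAA"   # stop codons in all three + phases
STOP_CASSETTE_REV <- "TTTATTTATTTA"   # stop codons in all three - phases
RUN_CODONS <- c("TTA", "CTA", "TCA")  # sense Leu/Leu/Ser; antisense stops
# eight sense-non-stop codons that plant stops in the two shifted forward
# phases (TAA at +1, TGA at +2) and antisense-stop trigrams in the two
# shifted reverse phases, interrupting every frame except the planted one
PHASE_BREAKER <- c("TTA", "AAA", "ATT", "AAA", "CAT", "TAC", "CAT", "GAT")

#' Generate a nucleotide sequence with a planted stop-free run
#'
#' Builds a sequence whose longest uninterrupted (stop-free) codon run in
#' the stated frame has exactly the planted length, while every other frame
#' is strictly shorter. The background alternates stop cassettes covering
#' all three phases of both strands, and run codons are drawn from
#' `{TTA, CTA, TCA}`, whose antisense codons are all stops, so the result
#' is verifiable by construction; a generation-time self-check runs
#' [six_frame_longest()] and fails loudly on any violation.
#'
#' @param length total sequence length (nt).
#' @param planted_run_codons length of the planted run (>= 9 codons, so it
#'   dominates the <= 8-codon gaps of the cassette background).
#' @param frame one of +1, +2, +3, -1, -2, -3.
#' @param seed integer seed (run codon choice and run placement).
#' @param fasta optional output FASTA path (record name carries the truth).
#' @param ground_truth optional JSON sidecar path.
#' @return list with `seq`, `frame`, `planted_run_codons` and the
#'   six-frame scan of the generated sequence.
#' @export
gen_pseudogene_seq <- function(length, planted_run_codons, frame = 1,
                               seed = 1, fasta = NULL, ground_truth = NULL) {
  stopifnot(frame %in% c(1, 2, 3, -1, -2, -3), planted_run_codons >= 9)
  set.seed(seed)
  p <- as.integer(planted_run_codons)
  offset <- abs(frame) - 1L
  core_len <- 3L * p
  if (core_len + offset > length)
    stop("planted run of ", p, " codons does not fit in ", length,
         " nt (frame ", frame, ")")
  bg <- paste0(STOP_CASSETTE_FWD, STOP_CASSETTE_REV)
  bg_fill <- function(n) {
    if (n <= 0) return("")
    substr(strrep(bg, ceiling(n / nchar(bg))), 1, n)
  }
  build <- function() {
    codons <- sample(RUN_CODONS, p, replace = TRUE)
    # drop the phase breaker near the middle so no other frame can run
    # uninterrupted through the planted region
    nb <- base::length(PHASE_BREAKER)
    if (p > nb) {
      lo <- max(1L, (p - nb) %/% 2L - 2L)
      hi <- min(p - nb + 1L, (p - nb) %/% 2L + 3L)
      at <- sample(seq(lo, hi), 1)
      codons[at:(at + nb - 1L)] <- PHASE_BREAKER
    } else {
      codons[seq_len(min(nb, p))] <- PHASE_BREAKER[seq_len(min(nb, p))]
    }
    run <- paste(codons, collapse = "")
    avail <- length - offset - core_len
    core <- if (avail >= 6L) paste0("TAA", run, "TAA")
            else if (avail >= 3L) paste0(run, "TAA") else run
    inner <- length - offset - nchar(core)
    pre_len <- if (avail >= 6L && inner >= 3L)
      3L * (sample.int(inner %/% 3L + 1L, 1) - 1L) else 0L
    s <- paste0(bg_fill(offset + pre_len), core,
                bg_fill(length - offset - pre_len - nchar(core)))
    substr(s, 1, length)
  }
  s <- NULL
  for (attempt in 1:50) {
    cand <- build()
    if (frame < 0)
      cand <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(cand)))
    scan <- six_frame_longest(cand)
    got <- scan$frames$length[scan$frames$frame == frame]
    others <- scan$frames$length[scan$frames$frame != frame]
    if (got == p && all(others < p)) { s <- cand; break }
  }
  if (is.null(s))
    stop("generation self-check failed for frame ", frame, ", run ", p)
  if (!is.null(fasta)) {
    writeLines(c(sprintf(">planted_frame%+d_run%d", frame,
                         planted_run_codons), s), fasta)
  }
  if (!is.null(ground_truth))
    jsonlite::write_json(
      list(frame = frame, planted_run_codons = planted_run_codons,
           length = length, seed = seed),
      ground_truth, auto_unbox = TRUE)
  list(seq = s, frame = frame, planted_run_codons = planted_run_codons,
       scan = scan)
}
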