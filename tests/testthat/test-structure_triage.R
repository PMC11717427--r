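test_that("load_dimer_model round-trips the synthetic PDB fixture", {
  fx <- gen_dimer_fixture(len_bait = 50, len_prey = 40, n_bait = 5,
                          n_prey = 5, seed = 1,
                          outdir = withr::local_tempdir())
  mod <- load_dimer_model(fx$paths$coords, fx$paths$pae, fx$paths$scores)
  expect_equal(nchar(mod$bait$sequence), 50)
  expect_equal(nchar(mod$prey$sequence), 40)
  expect_equal(dim(mod$pae), c(90, 90))
  expect_true(all(mod$plddt >= 0))
  expect_equal(mod$score$iptm, 0.8)

  # PAE dimension mismatch
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pae = matrix(1, 89, 90)), bad)
  expect_error(load_dimer_model(fx$paths$coords, bad, fx$paths$scores),
               "dimension")

  # three-chain file
  three <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(fx$paths$coords)
  extra <- sub("( [AB])(\\d| )", " C\\2", grep("^ATOM", lines, value = TRUE)[1])
  substr(extra, 22, 22) <- "C"
  writeLines(c(lines[grep("^ATOM", lines)], extra, "END"), three)
  expect_error(load_dimer_model(three, fx$paths$pae, fx$paths$scores),
               "2 chains")

  expect_error(load_dimer_model("x.xyz", fx$paths$pae, fx$paths$scores),
               "format")
})

test_that("minimal mmCIF models load identically to PDB", {
  fx <- gen_dimer_fixture(len_bait = 8, len_prey = 6, n_bait = 2,
                          n_prey = 2, seed = 4,
                          outdir = withr::local_tempdir())
  pdb <- load_dimer_model(fx$paths$coords, fx$paths$pae, fx$paths$scores)
  cif <- withr::local_tempfile(fileext = ".cif")
  a <- rbind(pdb$bait$atoms, pdb$prey$atoms)
  writeLines(c(
    "data_synthetic", "loop_",
    paste0("_atom_site.", c("group_PDB", "type_symbol", "label_atom_id",
                            "label_comp_id", "auth_asym_id", "auth_seq_id",
                            "Cartn_x", "Cartn_y", "Cartn_z",
                            "B_iso_or_equiv")),
    sprintf("ATOM %s %s %s %s %d %.3f %.3f %.3f %.2f", a$element, a$atom,
            a$resname, a$chain, a$resno, a$x, a$y, a$z, a$b)), cif)
  mod <- load_dimer_model(cif, fx$paths$pae, fx$paths$scores)
  expect_equal(mod$bait$sequence, pdb$bait$sequence)
  expect_equal(mod$prey$ca, pdb$prey$ca, tolerance = 1e-6)
  expect_equal(constrained_pairs(mod)[, 1:2],
               constrained_pairs(pdb)[, 1:2])
})

test_that("ranking_score follows both published formulas", {
  expect_equal(ranking_score(model_score(1, 1)), 1)
  expect_equal(ranking_score(model_score(0.5, 0.5)), 0.5)
  expect_equal(ranking_score(model_score(0.5, 0.5, disorder_frac = 0.2,
                                         version = "AF3-like")), 0.6)
  expect_error(model_score(0.5, 0.5, version = "AF3-like"), "disorder")
  expect_error(model_score(1.5, 0.5))
})

test_that("constrained_pairs equals the brute-force double loop", {
  for (seed in 1:50) {
    nb <- sample(0:8, 1)
    np <- if (nb == 0) 0 else sample(max(1, nb %/% 3):min(20, nb * 8), 1)
    fx <- gen_dimer_fixture(len_bait = 30, len_prey = 25,
                            n_bait = min(nb, 30), n_prey = min(np, 25),
                            seed = seed, outdir = withr::local_tempdir())
    mod <- load_fixture(fx)
    got <- constrained_pairs(mod)
    oracle <- brute_pairs(mod)
    expect_equal(got[, c("res_bait", "res_prey")], oracle)
    # and the generator's planted truth is recovered exactly
    expect_equal(got[, c("res_bait", "res_prey")],
                 fx$truth$pairs[, c("res_bait", "res_prey")])
  }
})

test_that("threshold boundaries are strict and symmetric in PAE", {
  fx <- gen_dimer_fixture(len_bait = 12, len_prey = 12, n_bait = 3,
                          n_prey = 3, contact_distance = 5, seed = 7,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  # contacts sit at 5 A (PDB stores 3 decimals): bracket the limit
  expect_equal(nrow(constrained_pairs(mod, dist_max = 4.99)), 0)
  expect_equal(nrow(constrained_pairs(mod, dist_max = 5.01)), 3)
  # a pair at exactly the distance limit is excluded (strict <)
  exact <- mod
  p1 <- fx$truth$pairs[1, ]
  exact$prey$ca[p1$res_prey, ] <- exact$bait$ca[p1$res_bait, ] + c(0, 6, 0)
  cpe <- constrained_pairs(exact)
  expect_false(any(cpe$res_bait == p1$res_bait &
                     cpe$res_prey == p1$res_prey))
  exact$prey$ca[p1$res_prey, ] <-
    exact$bait$ca[p1$res_bait, ] + c(0, 5.999, 0)
  cpi <- constrained_pairs(exact)
  expect_true(any(cpi$res_bait == p1$res_bait & cpi$res_prey == p1$res_prey))
  # PAE asymmetry: one direction above the cut kills the pair
  p <- fx$truth$pairs[1, ]
  la <- nchar(mod$bait$sequence)
  mod$pae[p$res_bait, la + p$res_prey] <- 4
  mod$pae[la + p$res_prey, p$res_bait] <- 6
  cp <- constrained_pairs(mod)
  expect_false(any(cp$res_bait == p$res_bait & cp$res_prey == p$res_prey))
  # PAE exactly at the limit is excluded too
  mod$pae[la + p$res_prey, p$res_bait] <- 5
  cp5 <- constrained_pairs(mod)
  expect_false(any(cp5$res_bait == p$res_bait & cp5$res_prey == p$res_prey))
})

test_that("relaxing thresholds never removes pairs; tightening never adds", {
  fx <- gen_dimer_fixture(len_bait = 25, len_prey = 25, n_bait = 6,
                          n_prey = 6, seed = 11,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  key <- function(d) paste(d$res_bait, d$res_prey)
  for (pm in c(3, 5, 9, 25)) for (dm in c(4, 6, 10)) {
    tight <- key(constrained_pairs(mod, pm, dm))
    loose <- key(constrained_pairs(mod, pm + 2, dm + 2))
    expect_true(all(tight %in% loose))
  }
})

test_that("interaction verdicts follow the v1/v2 truth tables", {
  tmp <- withr::local_tempdir()
  # ranking 0.75, n_prey 25 >= 20 -> v1 true
  fx <- gen_dimer_fixture(len_bait = 60, len_prey = 50, n_bait = 25,
                          n_prey = 25, iptm = 0.85, ptm = 0.35, seed = 2,
                          outdir = tmp, prefix = "a")
  call <- call_interaction(load_fixture(fx))
  expect_equal(call$ranking, 0.75)
  expect_true(call$passes_v1)
  expect_true(call$passes_v2)  # 625 > 100

  # boundary: n_bait 5 x n_prey 19 -> v1 false (19 < 20), v2 false (95 <= 100)
  fx2 <- gen_dimer_fixture(len_bait = 60, len_prey = 50, n_bait = 5,
                           n_prey = 19, iptm = 0.85, ptm = 0.35, seed = 3,
                           outdir = tmp, prefix = "b")
  call2 <- call_interaction(load_fixture(fx2))
  expect_equal(c(call2$n_bait, call2$n_prey), c(5L, 19L))
  expect_false(call2$passes_v1)
  expect_false(call2$passes_v2)

  # boundary: 6 x 19 -> v1 false, v2 true (114 > 100)
  fx3 <- gen_dimer_fixture(len_bait = 60, len_prey = 50, n_bait = 6,
                           n_prey = 19, iptm = 0.85, ptm = 0.35, seed = 4,
                           outdir = tmp, prefix = "c")
  call3 <- call_interaction(load_fixture(fx3))
  expect_equal(c(call3$n_bait, call3$n_prey), c(6L, 19L))
  expect_false(call3$passes_v1)
  expect_true(call3$passes_v2)

  # empty pair set fails both regardless of ranking
  fx0 <- gen_dimer_fixture(len_bait = 30, len_prey = 30, n_bait = 0,
                           n_prey = 0, iptm = 0.99, ptm = 0.99, seed = 5,
                           outdir = tmp, prefix = "d")
  call0 <- call_interaction(load_fixture(fx0))
  expect_false(call0$passes_v1 || call0$passes_v2)
})

test_that("verdicts are pure functions of pairs and ranking", {
  fx <- gen_dimer_fixture(len_bait = 40, len_prey = 40, n_bait = 8,
                          n_prey = 12, seed = 6,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  pairs <- constrained_pairs(mod)
  set.seed(99)
  for (k in 1:50) {
    mr <- runif(1, 0, 1); mp <- sample(1:30, 1); mx <- sample(10:200, 1)
    call <- call_interaction(mod, pairs, min_rank = mr,
                             min_prey_residues = mp, min_product = mx)
    expect_identical(call$passes_v1, call$ranking > mr && call$n_prey >= mp)
    expect_identical(call$passes_v2,
                     call$ranking > mr && call$n_bait * call$n_prey > mx)
  }
})

test_that("single-sphere SASA matches the closed form within 2%", {
  for (r in c(1.2, 1.52, 1.7, 1.9)) {
    got <- shrake_rupley(matrix(0, 1, 3), r)$total
    expect_equal(got, 4 * pi * (r + 1.4)^2, tolerance = 0.02)
  }
})

test_that("buried area is nonnegative, symmetric, zero when separated", {
  fx <- gen_dimer_fixture(len_bait = 20, len_prey = 18, n_bait = 4,
                          n_prey = 4, seed = 8,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  pairs <- constrained_pairs(mod)
  area <- interface_area(mod, pairs)
  expect_gte(area$buried_area, 0)
  expect_equal(area$area_norm, area$buried_area / (20 * 18))

  # chain-order symmetry
  flipped <- mod
  flipped$bait <- mod$prey; flipped$prey <- mod$bait
  fpairs <- pairs
  fpairs$res_bait <- pairs$res_prey; fpairs$res_prey <- pairs$res_bait
  area2 <- interface_area(flipped, fpairs)
  expect_equal(area2$buried_area, area$buried_area, tolerance = 1e-9)

  # empty selection
  expect_equal(interface_area(mod, pairs[0, ])$buried_area, 0)

  # two far-apart single-atom selections bury nothing
  sep <- mod
  sep$prey$atoms[, c("x", "y", "z")] <-
    sep$prey$atoms[, c("x", "y", "z")] + 500
  sep$prey$ca <- sep$prey$ca + 500
  expect_lt(interface_area(sep, pairs)$buried_area, 1e-6)

  # contacting selections bury a positive area
  expect_gt(area$buried_area, 0)
})

test_that("constrained_profile marks exactly the touched residues", {
  fx <- gen_dimer_fixture(len_bait = 30, len_prey = 25, n_bait = 5,
                          n_prey = 5, seed = 9,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  pairs <- constrained_pairs(mod)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  prof <- constrained_profile(mod, pairs, path = tsv)
  expect_equal(which(prof$bait), sort(unique(pairs$res_bait)))
  expect_equal(which(prof$prey), sort(unique(pairs$res_prey)))
  expect_equal(sum(read.delim(tsv)$constrained), 10)

  none <- constrained_profile(mod, pairs[0, ])
  expect_false(any(none$bait) || any(none$prey))
})

test_that("superpose_rmsd is rigid-invariant and recovers displacements", {
  fx <- gen_dimer_fixture(len_bait = 30, len_prey = 25, n_bait = 4,
                          n_prey = 4, seed = 10,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  expect_lt(superpose_rmsd(mod, mod), 1e-9)

  moved <- make_translated_copy(mod)
  expect_lt(superpose_rmsd(mod, moved), 1e-6)
  expect_lt(superpose_rmsd(mod, moved, scope = "complex"), 1e-6)

  # partner translated 10 A after anchor alignment
  shifted <- mod
  shifted$prey$ca <- sweep(mod$prey$ca, 2, c(0, 0, 10), "+")
  expect_equal(superpose_rmsd(mod, shifted), 10, tolerance = 1e-6)

  other <- gen_dimer_fixture(len_bait = 30, len_prey = 26, n_bait = 4,
                             n_prey = 4, seed = 12,
                             outdir = withr::local_tempdir())
  expect_error(superpose_rmsd(mod, load_fixture(other)), "sequence")
})

test_that("convergence_table ranks models by RMSD from the top model", {
  fx <- gen_dimer_fixture(len_bait = 30, len_prey = 25, n_bait = 4,
                          n_prey = 4, iptm = 0.9, ptm = 0.9, seed = 13,
                          outdir = withr::local_tempdir())
  top <- load_fixture(fx)
  displace <- function(m, dz, iptm) {
    m$prey$ca <- sweep(m$prey$ca, 2, c(0, 0, dz), "+")
    m$score <- model_score(iptm, 0.5)
    m
  }
  models <- list(best = top, near = displace(top, 4, 0.7),
                 far = displace(top, 25, 0.5))
  tab <- convergence_table(models)
  expect_equal(tab$model, c("best", "near", "far"))
  expect_equal(tab$rmsd, c(0, 4, 25), tolerance = 1e-6)

  dup <- convergence_table(list(top, top))
  expect_true(all(dup$rmsd < 1e-9))
  single <- convergence_table(list(only = top))
  expect_equal(single$rmsd, 0)
})

test_that("interface_concordance compares constrained prey footprints", {
  fx <- gen_dimer_fixture(len_bait = 60, len_prey = 50, n_bait = 22,
                          n_prey = 22, iptm = 0.9, ptm = 0.9, seed = 14,
                          outdir = withr::local_tempdir())
  mod <- load_fixture(fx)
  call <- call_interaction(mod)
  expect_true(call$passes_v1)
  same <- interface_concordance(call, call)
  expect_equal(same$verdict, "similar_interface")
  expect_equal(same$overlap, 1)

  # disjoint footprints, both passing
  shifted <- call
  shifted$pairs$res_prey <- shifted$pairs$res_prey %% 50 + 1
  shifted$pairs$res_prey <-
    setdiff(1:50, call$pairs$res_prey)[seq_len(nrow(call$pairs))]
  diff_call <- interface_concordance(call, shifted)
  expect_equal(diff_call$verdict, "different_interface")

  # overlap exactly at the threshold counts as similar (inclusive)
  half <- call
  keep <- unique(call$pairs$res_prey)
  at <- interface_concordance(call, call, overlap_min = 1)
  expect_equal(at$verdict, "similar_interface")

  fail <- call; fail$passes_v1 <- FALSE
  expect_equal(interface_concordance(call, fail)$verdict, "one_sided")
  expect_equal(interface_concordance(fail, fail)$verdict, "neither")
})

test_that("export_network writes GraphML that re-parses isomorphically", {
  tmp <- withr::local_tempdir()
  mk <- function(bait, prey, seed, nb, np)
    call_interaction(load_fixture(
      gen_dimer_fixture(len_bait = 30, len_prey = 30, n_bait = nb,
                        n_prey = np, seed = seed, outdir = tmp,
                        prefix = paste0(bait, prey))), min_rank = 0.5) |>
      (\(cl) { cl$pair_id <- c(bait = bait, prey = prey); cl })()
  calls <- list(mk("RDE3", "X1", 1, 5, 5), mk("RDE3", "X2", 2, 4, 6),
                mk("RDE8", "X1", 3, 3, 3))
  gml <- file.path(tmp, "net.graphml")
  tsv <- file.path(tmp, "net.tsv")
  g <- export_network(calls, area_norm = c(0.1, 0.2, 0.3),
                      support = c(TRUE, FALSE, FALSE),
                      graphml = gml, tsv = tsv)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 3)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::isomorphic(g, back))
  expect_equal(sort(igraph::E(back)$ranking), sort(igraph::E(g)$ranking))
  expect_equal(nrow(read.delim(tsv)), 3)

  expect_error(export_network(list(calls[[1]], calls[[1]])), "duplicate")
  empty <- export_network(list(), graphml = file.path(tmp, "e.graphml"))
  expect_equal(igraph::vcount(empty), 0)
  expect_true(file.exists(file.path(tmp, "e.graphml")))
})
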