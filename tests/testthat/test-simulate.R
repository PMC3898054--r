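# Simulation engine: determinism, distributional calibration, injection
# bookkeeping, and TP/FP scoring.

test_that("random trees are deterministic, binary, with exponential lengths", {
  t1 <- random_tree(10, seed = 3)
  t2 <- random_tree(10, seed = 3)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_equal(nrow(extract_clusters(t1)), 7)   # m - 3 for binary
  t4 <- random_tree(4, seed = 1)
  expect_equal(nrow(extract_clusters(t4)), 1)   # one internal branch
  # pooled branch lengths agree with the exponential rate
  lens <- unlist(lapply(1:150, function(i)
    random_tree(16, seed = i, br_rate = 10)$edge.length))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 0.1), 3 * se)
  expect_true(all(lens > 0))
})

test_that("clock noise scales by 1 + a*x with the right mean", {
  t <- random_tree(8, seed = 5)
  expect_identical(apply_clock_noise(t, a = 0)$edge.length, t$edge.length)
  factors <- unlist(lapply(1:400, function(i) {
    tn <- apply_clock_noise(t, a = 0.8, seed = i)
    tn$edge.length / t$edge.length
  }))
  se <- sd(factors) / sqrt(length(factors))
  expect_lt(abs(mean(factors) - 1.8), 3 * se)   # E[1 + 0.8 Exp(1)] = 1.8
  expect_true(all(factors >= 1))
})

test_that("HKY evolution is deterministic and respects edge cases", {
  t <- random_tree(6, seed = 7)
  m1 <- evolve_hky(t, 100, seed = 9)
  m2 <- evolve_hky(t, 100, seed = 9)
  expect_identical(unclass(m1), unclass(m2))
  # zero-length tree: identical sequences everywhere
  tz <- t; tz$edge.length <- rep(0, nrow(t$edge))
  mz <- evolve_hky(tz, 50, seed = 1)
  expect_true(all(apply(unclass(mz), 2, function(x) length(unique(x)) == 1)))
})

test_that("transition/transversion counts match the K80 closed form", {
  # equal frequencies and TS/TV = 2 make the generator a K80 process with
  # kappa = 4 (alpha = 2/3, beta = 1/6 after scaling to 1 sub/site).  The
  # observed transition/transversion fractions at divergence t have the
  # closed forms
  #   P_ts(t) = 1/4 + 1/4 e^(-4 beta t) - 1/2 e^(-2(alpha+beta) t)
  #   P_tv(t) = 1/2 - 1/2 e^(-4 beta t)
  # (computed here independently of the package's rate-matrix code).
  al <- 2 / 3; be <- 1 / 6; t_div <- 0.2
  p_ts <- 0.25 + 0.25 * exp(-4 * be * t_div) - 0.5 * exp(-2 * (al + be) * t_div)
  p_tv <- 0.5 - 0.5 * exp(-4 * be * t_div)
  tr <- ape::read.tree(text = "(a:0.0001,b:0.0001,c:0.2);")
  attr(tr, "taxa") <- c("a", "b", "c")
  n <- 100000
  msa <- evolve_hky(tr, n, tstv = 2, gamma_shape = Inf, seed = 13)
  a <- unclass(msa)["a", ]; c_ <- unclass(msa)["c", ]
  pur <- c("A", "G")
  is_ts <- (a %in% pur) == (c_ %in% pur)
  ts <- sum(a != c_ & is_ts); tv <- sum(a != c_ & !is_ts)
  # binomial 4-sigma windows around the closed-form expectations
  expect_lt(abs(ts - n * p_ts), 4 * sqrt(n * p_ts * (1 - p_ts)))
  expect_lt(abs(tv - n * p_tv), 4 * sqrt(n * p_tv * (1 - p_tv)))
  # with Gamma(1) rates the exponentials average to 1/(1 + c t)
  msa_g <- evolve_hky(tr, n, tstv = 2, gamma_shape = 1, seed = 17)
  p_ts_g <- 0.25 + 0.25 / (1 + 4 * be * t_div) - 0.5 / (1 + 2 * (al + be) * t_div)
  p_tv_g <- 0.5 - 0.5 / (1 + 4 * be * t_div)
  ag <- unclass(msa_g)["a", ]; cg <- unclass(msa_g)["c", ]
  is_ts_g <- (ag %in% pur) == (cg %in% pur)
  tsg <- sum(ag != cg & is_ts_g); tvg <- sum(ag != cg & !is_ts_g)
  expect_lt(abs(tsg - n * p_ts_g), 4 * sqrt(n * p_ts_g * (1 - p_ts_g)))
  expect_lt(abs(tvg - n * p_tv_g), 4 * sqrt(n * p_tv_g * (1 - p_tv_g)))
})

test_that("gamma rate heterogeneity spreads per-site divergence", {
  tr <- ape::read.tree(text = "(a:0.0001,b:0.0001,c:0.75);")
  attr(tr, "taxa") <- c("a", "b", "c")
  flat <- evolve_hky(tr, 30000, gamma_shape = Inf, seed = 3)
  hot <- evolve_hky(tr, 30000, gamma_shape = 0.3, seed = 3)
  # strong heterogeneity concentrates change in fewer sites: lower mean
  # divergence at equal branch length
  pd <- function(m) mean(unclass(m)["a", ] != unclass(m)["c", ])
  expect_lt(pd(hot), pd(flat))
})

test_that("injection records truth exactly and zero events is the identity", {
  cfg <- simulation_config(n_taxa = 10, seq_length = 300, n_events = 2,
                           event_fraction = 0.2, seed = 17)
  tr <- random_tree(10, seed = 19)
  msa <- evolve_hky(tr, 300, seed = 23)
  z <- inject_recombination(msa, tr, 0, cfg, seed = 29)
  expect_identical(unclass(z$msa), unclass(msa))
  expect_equal(nrow(z$truth), 0)
  inj <- inject_recombination(msa, tr, 2, cfg, seed = 29)
  expect_equal(nrow(inj$truth), 2)
  expect_true(all(inj$truth$start >= 1 & inj$truth$end <= 300))
  expect_true(all(inj$truth$end - inj$truth$start + 1 == 60))
  # blocks are disjoint
  expect_true(inj$truth$start[2] > inj$truth$end[1] ||
                inj$truth$start[1] > inj$truth$end[2])
  # donor and recipient disjoint, and the union conflicts with the tree
  taxa <- rownames(msa)
  for (i in 1:2) {
    D <- netcons:::key_to_side(inj$truth$donor[i])
    P <- netcons:::key_to_side(inj$truth$recipient[i])
    expect_false(any(D & P))
    expect_false(netcons:::canon_key(D | P) %in%
                   extract_clusters(tr, taxa)$key)
  }
  # outside the blocks the alignment is untouched
  keep <- setdiff(seq_len(300), unlist(lapply(1:2, function(i)
    inj$truth$start[i]:inj$truth$end[i])))
  expect_identical(unclass(inj$msa)[, keep], unclass(msa)[, keep])
})

test_that("injected blocks move the local tree toward donor+recipient", {
  # stochastic: the inside-block NJ tree should display the joined cluster in
  # a clear majority of seeds, and the outside-block tree should not drift
  hits_in <- 0L; hits_out <- 0L
  for (seed in 1:8) {
    cfg <- simulation_config(n_taxa = 12, seq_length = 400, n_events = 1,
                             event_fraction = 0.4, seed = seed, noise_a = 0.4)
    ds <- simulate_dataset(cfg)
    taxa <- rownames(ds$msa)
    blk <- ds$truth$start[1]:ds$truth$end[1]
    inside <- nj_tree(distance_matrix(netcons:::msa_slice(ds$msa, blk),
                                      "JC69"), taxa)
    outside <- nj_tree(distance_matrix(
      netcons:::msa_slice(ds$msa, setdiff(seq_len(400), blk)), "JC69"), taxa)
    joined <- netcons:::canon_key(netcons:::key_to_side(ds$truth$donor[1]) |
                                  netcons:::key_to_side(ds$truth$recipient[1]))
    hits_in <- hits_in + (joined %in% extract_clusters(inside, taxa)$key)
    hits_out <- hits_out + (joined %in% extract_clusters(outside, taxa)$key)
  }
  expect_gte(hits_in, 5)
  expect_lte(hits_out, 2)
})

test_that("score_detections is direction-aware and order-invariant", {
  truth <- data.frame(donor = c("1000", "0010"), recipient = c("0100", "0001"),
                      start = c(1, 50), end = c(40, 90),
                      stringsAsFactors = FALSE)
  found_ok <- data.frame(donor = truth$donor, recipient = truth$recipient,
                         direction = c("forward", "forward"),
                         stringsAsFactors = FALSE)
  ev <- score_detections(truth, found_ok)
  expect_equal(ev$tp, 2); expect_equal(ev$fp, 0)
  # wrong donor: fp
  bad <- found_ok; bad$donor[1] <- "0001"
  ev2 <- score_detections(truth, bad)
  expect_equal(ev2$tp, 1); expect_equal(ev2$fp, 1)
  # reversed orientation: fp when directed, tp when undirected
  rev1 <- data.frame(donor = truth$recipient[1], recipient = truth$donor[1],
                     direction = "forward", stringsAsFactors = FALSE)
  expect_equal(score_detections(truth, rev1)$tp, 0)
  rev1$direction <- "undirected"
  expect_equal(score_detections(truth, rev1)$tp, 1)
  # permutation invariance
  ev3 <- score_detections(truth, found_ok[2:1, ])
  expect_equal(ev3$tp, 2)
})

test_that("the whole generator chain is deterministic under one seed", {
  cfg <- simulation_config(n_taxa = 8, seq_length = 150, n_events = 1,
                           event_fraction = 0.3, seed = 37)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(unclass(a$msa), unclass(b$msa))
  expect_identical(a$truth, b$truth)
})
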