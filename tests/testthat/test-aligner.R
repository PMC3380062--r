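res_default <- resolution_set()

test_that("scan_m_clusters splits the worked example into two clusters", {
  res <- resolution_set(mode = "fixed_da", delta_m_fixed = 0.001)
  mz <- c(130.033, 130.034, 130.035, 130.409, 130.410, 130.411)
  cl <- scan_m_clusters(mz, res)
  expect_equal(cl, list(1:3, 4:6))
  expect_equal(scan_m_clusters(130.5, res), list(1L))
  expect_equal(scan_m_clusters(numeric(0), res), list())
  expect_error(scan_m_clusters(c(2, 1), res), "sorted")
})

test_that("scan_m_clusters matches an independent gap-scan oracle on random masses", {
  set.seed(3)
  for (rep in 1:10) {
    mz <- sort(runif(50, 1, 500))
    res <- resolution_set(eps_ppm = sample(c(10, 100, 1000), 1))
    got <- scan_m_clusters(mz, res)
    want <- oracle_gap_clusters(mz, function(prev, cur)
      pad(2 * delta_m(res, cur)))
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("scan_r_clusters follows the doubled rt tolerance", {
  res <- res_default
  cl <- scan_r_clusters(c(10.0, 10.3, 10.6, 12.0), res)
  expect_equal(cl, list(1:3, 4L))  # span 0.6 = 2*delta_r stays together
  expect_equal(scan_r_clusters(5, res), list(1L))
  expect_equal(scan_r_clusters(c(1, 1.2, 1.5), res), list(1:3))
  expect_error(scan_r_clusters(c(3, 1), res), "sorted")
  set.seed(4)
  for (rep in 1:10) {
    rt <- sort(runif(40, 1, 27))
    got <- scan_r_clusters(rt, res)
    want <- oracle_gap_clusters(rt, function(prev, cur) pad(2 * res$delta_r))
    expect_equal(got, want)
  }
})

test_that("consensus_centre is the midrange of the extremes", {
  expect_equal(consensus_centre(c(1, 1, 1), c(130.033, 130.034, 130.035))[["mz"]],
               130.034)
  expect_equal(consensus_centre(c(1, 1, 1), c(130.409, 130.411, 130.410))[["mz"]],
               130.410)
  expect_equal(consensus_centre(2.5, 99)[["rt"]], 2.5)  # single member
  expect_error(consensus_centre(numeric(0), numeric(0)), "non-empty")
})

test_that("form_consensus accepts clean clusters and resolves collisions", {
  res <- res_default
  # one feature per map, all inside tolerance
  mem <- data.frame(uid = 1:3, rt = c(10.0, 10.1, 10.2),
                    mz = c(200.000, 200.001, 200.0005), map = 1:3)
  fc <- form_consensus(mem, 3L, res)
  expect_true(fc$accepted)
  expect_equal(fc$centre_rt, 10.1)

  # two same-map features: the one closer to the centre is retained
  mem2 <- data.frame(uid = 1:3, rt = c(10.0, 10.05, 10.2),
                     mz = c(200.0, 200.0002, 200.0015), map = c(1, 2, 2))
  fc2 <- form_consensus(mem2, 2L, res)
  expect_true(fc2$accepted)
  expect_setequal(fc2$members$uid, c(1, 2))
  expect_equal(fc2$excluded$uid, 3)

  # a member violating the resolution against the centre is excluded first
  mem3 <- data.frame(uid = 1:3, rt = c(10.0, 10.1, 11.5),
                     mz = c(200.0, 200.001, 200.001), map = 1:3)
  fc3 <- form_consensus(mem3, 2L, res)
  expect_true(fc3$accepted)
  expect_setequal(fc3$members$uid, c(1, 2))
  # and the same cluster demanded at n = 3 is rejected, not forced
  expect_false(form_consensus(mem3, 3L, res)$accepted)
})

test_that("form_consensus agrees with the exhaustive subset oracle on tight clouds", {
  res <- res_default
  set.seed(17)
  for (rep in 1:30) {
    p <- sample(2:8, 1)
    rt0 <- runif(1, 2, 25); mz0 <- runif(1, 10, 480)
    mem <- data.frame(uid = seq_len(p),
                      rt = rt0 + runif(p, -0.4, 0.4) * res$delta_r,
                      mz = mz0 + runif(p, -0.4, 0.4) * delta_m(res, mz0),
                      map = sample(1:4, p, TRUE))
    want <- oracle_best_subset(mem, res)
    fc <- form_consensus(mem, length(want), res)
    expect_true(fc$accepted, info = paste("rep", rep))
    expect_true(oracle_valid_block(fc$members, res))
    if (!anyDuplicated(mem$map)) expect_setequal(fc$members$uid, mem$uid[want])
  }
})

test_that("align_features recovers noise-free two-map truth exactly", {
  sim <- simulate_two_map(30, 30, gamma = 0, res = res_default, seed = 5)
  al <- align_features(sim$features, res_default)
  expect_equal(sensitivity(al, sim), 100)
  expect_equal(specificity(al, sim), 100)
  # features of each aligned TSM have identical coordinates at gamma = 0
  expect_equal(al$size_counts, c(30L, 30L))
})

test_that("align_features handles empty and degenerate inputs", {
  empty <- ft(numeric(0), numeric(0), integer(0), numeric(0))
  al <- align_features(empty, res_default)
  expect_equal(nrow(al$consensuses), 0L)
  expect_equal(al$n_features, 0L)

  # all features identical: one consensus per map-collision group
  d <- ft(rt = rep(10, 5), mz = rep(200, 5), map = c(1, 1, 1, 2, 2))
  al2 <- align_features(d, res_default)
  expect_equal(sort(al2$consensuses$size), c(1L, 2L, 2L))
  expect_equal(sum(al2$consensuses$size), 5L)
  # collision-freedom: no consensus holds two features of one map
  for (b in alignment_blocks(al2))
    expect_false(anyDuplicated(d$map[match(b, d$uid)]) > 0)
})

test_that("conservation and collision-freedom hold on random multi-map data", {
  res <- res_default
  for (seed in 1:6) {
    sim <- simulate_multi_map(n_maps = 6, n_per_size = rep(4, 6),
                              gamma = 1, res = res, seed = 100 + seed)
    al <- align_features(sim$features, res)
    N <- nrow(sim$features)
    expect_equal(sum(seq_along(al$size_counts) * al$size_counts), N)
    expect_equal(sort(al$assignments$uid), sim$features$uid)
    feats <- sim$features
    for (b in alignment_blocks(al)) {
      rows <- feats[match(b, feats$uid), ]
      expect_false(anyDuplicated(rows$map) > 0)
      # every member within the resolution of its consensus centre
      ctr <- consensus_centre(rows$rt, rows$mz)
      expect_true(all(abs(rows$rt - ctr[["rt"]]) <= pad(res$delta_r)))
      expect_true(all(abs(rows$mz - ctr[["mz"]]) <=
                        pad(delta_m(res, ctr[["mz"]]))))
    }
  }
})

test_that("align_features matches the exhaustive partition oracle on small data", {
  res <- res_default
  for (seed in 1:8) {
    sim <- simulate_multi_map(n_maps = 4, n_per_size = c(3, 2, 2, 2),
                              gamma = 1, res = res, seed = 500 + seed)
    stopifnot(nrow(sim$features) <= 30)
    al <- align_features(sim$features, res)
    want <- oracle_align(sim$features, res)
    expect_equal(canonical_blocks(alignment_blocks(al)),
                 canonical_blocks(want), info = paste("seed", seed))
  }
})

test_that("a planted consensus at the tolerance boundary is never split", {
  # greedy-scan safety: members sitting exactly on the resolution boundary
  res <- res_default
  K <- 4L
  rt0 <- 12; mz0 <- 300
  dm <- delta_m(res, mz0)
  d <- ft(rt = c(rt0 - res$delta_r, rt0, rt0, rt0 + res$delta_r,
                 rt0 + 10, rt0 - 10),
          mz = c(mz0, mz0 - dm, mz0 + dm, mz0, mz0 + 50, mz0 - 50),
          map = c(1, 2, 3, 4, 1, 2), n_maps = K)
  al <- align_features(d, res)
  blocks <- alignment_blocks(al)
  expect_true("1,2,3,4" %in% canonical_blocks(blocks))
  expect_equal(al$size_counts, c(2L, 0L, 0L, 1L))
})

test_that("alignment is deterministic", {
  sim <- simulate_two_map(50, 50, gamma = 1, res = res_default, seed = 9)
  a1 <- align_features(sim$features, res_default)
  a2 <- align_features(sim$features, res_default)
  expect_identical(a1, a2)
})

test_that("runtime scales sub-quadratically with dataset size", {
  res <- res_default
  sim1 <- simulate_two_map(400, 400, gamma = 1, res = res, seed = 31)
  sim2 <- simulate_two_map(1600, 1600, gamma = 1, res = res, seed = 32)
  t1 <- system.time(align_features(sim1$features, res))[["elapsed"]]
  t2 <- system.time(align_features(sim2$features, res))[["elapsed"]]
  ratio <- t2 / max(t1, 0.01)
  message(sprintf("scaling: N x4 -> time x%.1f (%.2fs -> %.2fs)",
                  ratio, t1, t2))
  expect_lt(ratio, 16)  # quadratic growth would give ~16
})
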