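test_that("trajectories satisfy the structural invariants", {
  for (seed in c(1, 7, 31)) {
    traj <- simulate_patient(af_params(), seed = seed)
    expect_true(all(traj$start < traj$end))
    expect_true(all(traj$start >= 0) && all(traj$end <= 100))
    if (nrow(traj) > 1) {
      expect_true(all(traj$end[-nrow(traj)] < traj$start[-1]))
    }
    # at most one censored episode, and only as the last one
    expect_lte(sum(traj$censored), 1)
    if (any(traj$censored)) {
      expect_true(traj$censored[nrow(traj)])
      expect_equal(traj$end[nrow(traj)], 100)
    }
    # SR + AF time partitions the horizon exactly
    af_time <- sum(traj$end - traj$start)
    gaps <- c(traj$start, 100) - c(0, traj$end)
    expect_equal(af_time + sum(gaps), 100, tolerance = 1e-9)
    expect_true(all(gaps >= 0))
  }
})

test_that("a fixed seed reproduces the trajectory to 12 significant digits", {
  a <- simulate_patient(af_params(), seed = 99)
  b <- simulate_patient(af_params(), seed = 99)
  expect_identical(sprintf("%.12g", a$start), sprintf("%.12g", b$start))
  expect_identical(sprintf("%.12g", a$end), sprintf("%.12g", b$end))
  expect_identical(a$censored, b$censored)
  c <- simulate_patient(af_params(), seed = 100)
  expect_false(isTRUE(all.equal(a$start[1], c$start[1])))
})

test_that("the compiled event loop replays through the exported R dynamics", {
  # same seed => same Exp(1) stream => the R reference loop built from
  # evolve_*, invert_*_hazard and the boost must reproduce the event times
  p <- af_params()
  for (seed in c(3, 17)) {
    cpp <- simulate_patient(p, seed = seed, horizon = 60)
    ref <- simulate_patient_ref(p, seed = seed, horizon = 60)
    expect_equal(nrow(cpp), nrow(ref))
    expect_equal(cpp$start, ref$start, tolerance = 1e-9)
    expect_equal(cpp$end, ref$end, tolerance = 1e-9)
    expect_identical(cpp$censored, ref$censored)
  }
})

test_that("constant-rate runs recover the telegraph-process closed forms", {
  # switching rates a (on) and r (off): AF fraction a/(a+r), mean episode 1/r
  a <- 20; r <- 50
  p <- make_fixture("constant_rate", activation = a, recovery = r)
  af_frac <- c(); durs <- c()
  for (seed in 1:5) {
    traj <- simulate_patient(p, seed = seed, check = FALSE)
    af_frac <- c(af_frac, sum(traj$end - traj$start) / 100)
    keep <- !traj$censored
    durs <- c(durs, traj$end[keep] - traj$start[keep])
  }
  expect_equal(mean(af_frac), a / (a + r), tolerance = 0.05)
  expect_equal(mean(durs), 1 / r, tolerance = 0.05)
})

test_that("baseline patients reach permanent AF with a qualifying episode", {
  thr <- time_conventions()$paroxysmal_threshold
  for (seed in c(2, 5, 8, 13)) {
    traj <- simulate_patient(af_params(), seed = seed)
    expect_true(traj$censored[nrow(traj)])
    expect_true(any(traj$end - traj$start >= thr))
  }
})

test_that("zero activation produces zero episodes", {
  p <- make_fixture("constant_rate", activation = 1e-12, recovery = 50)
  traj <- simulate_patient(p, seed = 4, check = FALSE)
  expect_equal(nrow(traj), 0)
})

test_that("inter-onset times match the thinning oracle (constant rates, KS)", {
  p <- make_fixture("constant_rate", activation = 8, recovery = 60)
  gaps <- function(simfun, seed_off) {
    out <- c()
    for (seed in 1:60) {
      tr <- simfun(p, seed = seed + seed_off, horizon = 2)
      if (nrow(tr) > 1) out <- c(out, diff(tr$start))
    }
    out
  }
  g_exact <- gaps(function(...) simulate_patient(..., check = FALSE), 0)
  g_thin <- gaps(thinning_oracle, 1000)
  expect_gt(length(g_exact), 500)
  expect_gt(length(g_thin), 500)
  ks <- suppressWarnings(stats::ks.test(g_exact, g_thin))
  expect_gt(ks$p.value, 0.01)
})

test_that("episode counts from a mid-life entry state match the thinning oracle", {
  # one year of baseline dynamics from age 60 with a fixed entry state
  p <- af_params()
  init <- function() af_state(t = 60, S = 0, Aepi = 50, Repi = 1000)
  n <- 400
  counts_exact <- vapply(1:n, function(s) {
    nrow(simulate_patient(p, seed = s, horizon = 61, init = init()))
  }, numeric(1))
  counts_thin <- vapply(1:n, function(s) {
    nrow(thinning_oracle(p, seed = s + 10000, horizon = 61, init = init()))
  }, numeric(1))
  # compare distributions on shared quantile bins (chi-square)
  edges <- unique(stats::quantile(c(counts_exact, counts_thin),
                                  probs = seq(0, 1, 0.2)))
  b1 <- table(cut(counts_exact, c(-Inf, edges[-1], Inf)))
  b2 <- table(cut(counts_thin, c(-Inf, edges[-1], Inf)))
  keep <- (b1 + b2) > 0
  chi <- suppressWarnings(stats::chisq.test(rbind(b1[keep], b2[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("a tenfold activation increase raises episode counts (paired seeds)", {
  p_lo <- make_fixture("constant_rate", activation = 2, recovery = 50)
  p_hi <- make_fixture("constant_rate", activation = 20, recovery = 50)
  inc <- vapply(1:20, function(seed) {
    n_lo <- nrow(simulate_patient(p_lo, seed, horizon = 5, check = FALSE))
    n_hi <- nrow(simulate_patient(p_hi, seed, horizon = 5, check = FALSE))
    n_hi > n_lo
  }, logical(1))
  # sign test: under no effect, P(>= 18/20 increases) < 1e-3
  expect_gte(sum(inc), 18)
})

test_that("trajectory files round-trip byte-identically", {
  traj <- simulate_patient(af_params(), seed = 21, horizon = 70)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(back, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_identical(unclass(attr(back, "params")),
                   unclass(attr(traj, "params")))
  expect_equal(attr(back, "horizon"), 70)
  expect_equal(attr(back, "seed"), 21)
})
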