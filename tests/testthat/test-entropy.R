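test_that("binning yields complete half-open 120 ms bins", {
  # 390 s at 120 Hz -> 3250 complete bins
  tr <- make_trace(rep(0, 46800))
  b <- bin_series(tr, 120)
  expect_equal(nrow(b), 3250)
  expect_true(all(b$displacement == 0))
  expect_true(all(b$valid))
  # trailing partial bin is discarded: 100 samples = 0.833 s -> 6 bins
  expect_equal(nrow(bin_series(make_trace(rep(0, 100)), 120)), 6)
  # 3-4-5 displacement between first and last sample of a bin
  yaw <- c(0, rep(1, 13), 3)
  pitch <- c(0, rep(1, 13), 4)
  b1 <- bin_series(make_trace(yaw, pitch), 120)
  expect_equal(b1$displacement[1], 5)
  expect_error(bin_series(tr, 0), "bin_ms")
})

test_that("mostly-invalid bins are flagged and excluded from displacement", {
  # at 120 Hz a 120 ms bin holds 14 or 15 samples; index bins explicitly
  n <- 450
  idx <- floor(((seq_len(n) - 1) / 120) / 0.12 + 1e-9) + 1L
  valid <- rep(TRUE, n)
  valid[idx == 2] <- FALSE                       # bin 2 fully invalid
  b3 <- which(idx == 3)
  valid[b3[seq_len(ceiling(length(b3) * 0.6))]] <- FALSE # bin 3 > 50% invalid
  b4 <- which(idx == 4)
  n_inv4 <- floor(length(b4) * 0.4)
  valid[b4[seq_len(n_inv4)]] <- FALSE            # bin 4 <= 50% invalid
  b <- bin_series(make_trace(rnorm(n), valid = valid), 120)
  expect_false(b$valid[2])
  expect_false(b$valid[3])
  expect_true(b$valid[4])
  expect_true(is.na(b$displacement[2]))
  # displacement uses first/last *valid* samples: bin 4's invalid samples sit
  # at an outlier value; the valid remainder is constant, so displacement 0
  yaw <- rep(0, n)
  yaw[b4] <- 7
  yaw[b4[seq_len(n_inv4)]] <- 99
  vb <- rep(TRUE, n)
  vb[b4[seq_len(n_inv4)]] <- FALSE
  b2 <- bin_series(make_trace(yaw, valid = vb), 120)
  expect_equal(b2$displacement[4], 0)
})

test_that("state assignment follows the policy contracts", {
  mk_bins <- function(disp) {
    structure(data.frame(start = seq_along(disp) * 0.12 - 0.12,
                         displacement = disp,
                         valid = !is.na(disp)),
              bin_ms = 120, class = c("bin_series", "data.frame"))
  }
  expect_equal(assign_states(mk_bins(c(0.1, 5.0, 0.2)), theta = 1),
               c("stay", "shift", "stay"))
  expect_equal(unique(assign_states(mk_bins(rep(0.3, 10)), theta = 1)),
               "stay")
  # invalid bins get the NA sentinel
  expect_equal(is.na(assign_states(mk_bins(c(0.1, NA, 3)))),
               c(FALSE, TRUE, FALSE))
  # quantile policy: k = 2 on 100 distinct displacements -> 50/50 occupancy
  set.seed(51)
  st <- assign_states(mk_bins(sample(seq(0.01, 1, length.out = 100))),
                      "displacement_quantiles", k = 2)
  expect_equal(sort(as.integer(table(st))), c(50L, 50L))
  # ties break toward the lower state
  st_tie <- assign_states(mk_bins(c(1, 1, 1, 2)), "displacement_quantiles",
                          k = 2)
  expect_equal(st_tie, c("q1", "q1", "q1", "q2"))
  expect_error(assign_states(mk_bins(c(1, 2)), "aoi_labels"), "gaze")
})

test_that("aoi state policy takes the majority label per bin", {
  s <- simulate_session(short_params(duration_s = 60, seed = 52))
  gaze <- reconstruct_gaze(s$eye, s$head)
  bins <- bin_series(gaze, 120)
  aoi <- assign_aoi(gaze, s$geometry)
  st <- assign_states(bins, "aoi_labels", aoi = aoi, trace = gaze)
  expect_equal(length(st), nrow(bins))
  expect_true(all(st[!is.na(st)] %in% c("central_screen", "device", "other")))
  # majority check on one bin by hand
  idx <- which(!is.na(st))[5]
  in_bin <- aoi[floor((gaze$samples$t - gaze$samples$t[1]) / 0.12 + 1e-9) + 1 == idx]
  expect_equal(st[idx], names(sort(table(in_bin), decreasing = TRUE))[1])
})

test_that("transition model counts consecutive valid pairs", {
  m <- transition_model(c("A", "B", "A", "B", "A"))
  expect_equal(m$n_pairs, 4)
  expect_equal(m$joint["A", "B"], 0.5)
  expect_equal(m$joint["B", "A"], 0.5)
  expect_equal(sum(m$joint), 1)
  # constant sequence: one occupied cell
  mc <- transition_model(rep("A", 10))
  expect_equal(unname(mc$joint[1, 1]), 1)
  # pairs spanning an invalid bin are dropped: A B NA A A -> pairs AB, AA
  mi <- transition_model(c("A", "B", NA, "A", "A"))
  expect_equal(mi$n_pairs, 2)
  expect_equal(unname(mi$counts["A", "B"]), 1)
  expect_equal(unname(mi$counts["A", "A"]), 1)
  expect_error(transition_model(c("A", NA, "B")), "consecutive")
  expect_error(transition_model(c("A", NA, NA)), "2 valid")
})

test_that("stationary probabilities equal the joint row marginals", {
  set.seed(53)
  for (i in 1:20) {
    st <- sample(letters[1:sample(2:4, 1)], 60, replace = TRUE)
    st[sample(60, 5)] <- NA
    if (sum(!is.na(st)) < 10) next
    m <- transition_model(st)
    expect_equal(m$p_i, rowSums(m$joint), tolerance = 1e-15)
    occ <- m$p_i > 0
    expect_equal(unname(rowSums(m$conditional[occ, , drop = FALSE])),
                 rep(1, sum(occ)), tolerance = 1e-12)
  }
})

test_that("conditional entropy reproduces closed forms", {
  # deterministic alternation: zero entropy
  alt <- conditional_entropy(transition_model(rep(c("A", "B"), 50)))
  expect_equal(alt$raw_bits, 0)
  expect_equal(alt$normalized, 0)
  # 2-state uniform i.i.d. chain: maximal entropy (AABB block has all four
  # pair types equally often)
  unif <- conditional_entropy(transition_model(c(rep(c("A", "A", "B", "B"), 25), "A")))
  expect_equal(unif$raw_bits, 1, tolerance = 1e-12)
  expect_equal(unif$normalized, 1, tolerance = 1e-12)
  # single state: normalized 0 by convention
  one <- conditional_entropy(transition_model(rep("A", 5)))
  expect_equal(one$normalized, 0)
})

test_that("chain entropy matches the stationary closed form", {
  # rows (0.9, 0.1) and (0.5, 0.5): pi = (5/6, 1/6),
  # H = 5/6 * H(0.9, 0.1) + 1/6 * 1 = 0.5575 bits
  closed <- markov_chain_entropy(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(closed, 0.5575, tolerance = 1e-4)
  P <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  set.seed(54)
  chain <- simulate_markov_chain(P, 2e5)
  got <- conditional_entropy(transition_model(c("A", "B")[chain]))
  expect_equal(got$raw_bits, closed, tolerance = 5e-3)
})

test_that("standard entropy equals brute-force enumeration to 1e-12", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    k <- sample(2:4, 1)
    st <- sample(LETTERS[1:k], n, replace = TRUE)
    if (i %% 3 == 0) st[sample(n, max(1, n %/% 10))] <- NA
    ok <- !is.na(st)
    if (sum(ok[-length(ok)] & ok[-1]) < 1) next
    m <- transition_model(st)
    for (mode in c("standard", "literal")) {
      got <- conditional_entropy(m, mode)
      exp <- brute_force_entropy(st, mode)
      expect_equal(got$raw_bits, exp$raw, tolerance = 1e-12)
      expect_equal(got$normalized, exp$normalized, tolerance = 1e-12)
    }
  }
})

test_that("entropy invariants: range, conditioning bound, label invariance", {
  set.seed(56)
  for (i in 1:30) {
    st <- sample(letters[1:3], 80, replace = TRUE,
                 prob = runif(3) + 0.1)
    m <- transition_model(st)
    h <- conditional_entropy(m)
    expect_gte(h$normalized, 0)
    expect_lte(h$normalized, 1)
    # conditioning reduces entropy: H(X_{t+1} | X_t) <= H(stationary)
    h_marg <- -sum(m$p_i[m$p_i > 0] * log2(m$p_i[m$p_i > 0]))
    expect_lte(h$raw_bits, h_marg + 1e-12)
    # permuting labels leaves entropy unchanged
    perm <- setNames(sample(c("x", "y", "z")), letters[1:3])
    h_perm <- conditional_entropy(transition_model(unname(perm[st])))
    expect_equal(h_perm$raw_bits, h$raw_bits, tolerance = 1e-12)
  }
})

test_that("deterministic chains and only they give zero standard entropy", {
  # deterministic cycle over 3 states
  cyc <- conditional_entropy(transition_model(rep(c("a", "b", "c"), 30)))
  expect_equal(cyc$raw_bits, 0)
  # any chain with a stochastic row is strictly positive
  pos <- conditional_entropy(transition_model(c("a", "a", "b", "a", "b", "b", "a")))
  expect_gt(pos$raw_bits, 0)
})

test_that("session entropy composes the stages and keeps provenance", {
  s <- simulate_session(short_params(duration_s = 60, seed = 57))
  r <- session_entropy(s, "eye")
  expect_s3_class(r, "entropy_result")
  expect_equal(r$effector, "eye")
  expect_equal(r$bin_ms, 120)
  expect_equal(r$n_bins, 500)
  expect_equal(r$policy, "displacement_threshold")
  # a session whose head never moves: gaze entropy == eye entropy
  p <- short_params(duration_s = 60, seed = 58, head_gain_yaw = 0,
                    head_gain_pitch = 0, noise_sd_head = 0)
  s0 <- simulate_session(p)
  expect_equal(session_entropy(s0, "gaze")$raw_bits,
               session_entropy(s0, "eye")$raw_bits, tolerance = 1e-9)
  # constant session: entropy 0
  const <- make_session(rep(3, 1200))
  expect_equal(session_entropy(const, "eye")$raw_bits, 0)
})

test_that("normalized entropy increases with generator randomness", {
  # small-scale version of the monotone-recovery property (sign test)
  set.seed(59)
  mean_ent <- function(r, seeds) {
    mean(vapply(seeds, function(sd) {
      p <- short_params(duration_s = 60, seed = sd, state_randomness = r)
      session_entropy(simulate_session(p), "eye")$normalized
    }, numeric(1)))
  }
  seeds <- sample.int(1e6, 8)
  ents <- vapply(c(0.1, 0.5, 0.9), mean_ent, numeric(1), seeds = seeds)
  expect_true(all(diff(ents) > 0))
})
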