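# Shared fixture builders; all fixtures are generated in code.

# Uniform-clock trace from explicit angle vectors.
make_trace <- function(yaw, pitch = rep(0, length(yaw)), rate = 120,
                       effector = "eye", valid = TRUE, t0 = 0) {
  t <- t0 + (seq_along(yaw) - 1) / rate
  effector_trace(t, yaw, pitch, valid = valid, effector = effector,
                 rate = rate)
}

# Short session for tests that only need structure, not the full scenario.
short_params <- function(condition = "optimal", group = "lower", seed = 1L,
                         duration_s = 60, ...) {
  p <- default_params(condition, group)
  p$duration_s <- duration_s
  p$seed <- as.integer(seed)
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  p
}

# Session built directly from traces (bypasses the generator).
make_session <- function(eye_yaw, eye_pitch = rep(0, length(eye_yaw)),
                         head_yaw = rep(0, length(eye_yaw)),
                         head_pitch = rep(0, length(eye_yaw)), rate = 120,
                         trials = data.frame(start = numeric(0),
                                             end = numeric(0))) {
  gaze_session(
    make_trace(eye_yaw, eye_pitch, rate, "eye"),
    make_trace(head_yaw, head_pitch, rate, "head"),
    trials = trials, participant = "T01", condition = "optimal",
    group = "lower"
  )
}

# Independent brute-force conditional entropy: explicit pair enumeration
# with double loops, no shared code with the package implementation.
brute_force_entropy <- function(states, mode = "standard") {
  n <- length(states)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    if (!is.na(states[i]) && !is.na(states[i + 1])) {
      pairs[[length(pairs) + 1]] <- c(states[i], states[i + 1])
    }
  }
  stopifnot(length(pairs) > 0)
  labs <- sort(unique(unlist(pairs)))
  k <- length(labs)
  joint <- matrix(0, k, k, dimnames = list(labs, labs))
  for (p in pairs) joint[p[1], p[2]] <- joint[p[1], p[2]] + 1
  joint <- joint / length(pairs)
  p_i <- rowSums(joint)
  H <- 0
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      if (joint[a, b] > 0) {
        if (mode == "standard") {
          H <- H - joint[a, b] * log2(joint[a, b] / p_i[a])
        } else {
          H <- H - p_i[a] * joint[a, b] * log2(joint[a, b])
        }
      }
    }
  }
  H <- unname(H)
  list(raw = H, normalized = if (k > 1) H / log2(k) else 0)
}

# Closed-form conditional entropy of a 2-state Markov chain from its
# transition rows, via the stationary distribution.
markov_chain_entropy <- function(row1, row2) {
  # stationary pi solves pi P = pi
  a <- row1[2]; b <- row2[1]
  pi1 <- b / (a + b)
  h <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  pi1 * h(row1) + (1 - pi1) * h(row2)
}

# Simulate a 2-state Markov chain (integer states 1/2) of length n.
simulate_markov_chain <- function(P, n, init = 1L) {
  u <- stats::runif(n)
  s <- integer(n)
  s[1] <- init
  for (i in 2:n) s[i] <- if (u[i] < P[s[i - 1], 1]) 1L else 2L
  s
}
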