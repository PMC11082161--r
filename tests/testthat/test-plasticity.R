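test_that("the STDP kernel evaluates its two exponential branches", {
  ah <- stdp_rule("asymmetric_anti_hebbian")
  hb <- stdp_rule("asymmetric_hebbian")
  expect_equal(stdp_kernel(20, ah), -exp(-1))
  expect_equal(stdp_kernel(-20, hb), -exp(-1))
  expect_lt(abs(stdp_kernel(-200, ah)), exp(-10) + 1e-12)
  # the simultaneous causally ordered pair takes the pre-post branch
  expect_equal(stdp_kernel(0, ah), ah$A_pre_post)
  # presets ordered (A_post_pre, A_pre_post)
  expect_equal(unlist(stdp_rule("symmetric_ltd")[c("A_post_pre", "A_pre_post")]),
               c(A_post_pre = -1, A_pre_post = -1))
  expect_equal(stdp_rule("sym-ltp")$A_pre_post, 1)
  expect_equal(stdp_rule("anti-hebb")$name, "asymmetric_anti_hebbian")
  expect_error(stdp_rule("nonsense"), "preset")
})

test_that("post-spike updates sum the kernel over the presynaptic history", {
  ltp <- stdp_rule("symmetric_ltp")
  h <- spike_history(2)
  # empty history: no-op
  r <- on_post_spike(c(0.5, 0.5), h, 100, ltp)
  expect_equal(r$weights, c(0.5, 0.5))
  # single pre spike one tau_stdp earlier
  h2 <- on_pre_spike(c(0.5, 0.5), h, 1, 80, ltp)$hist
  r2 <- on_post_spike(c(0.5, 0.5), h2, 100, ltp)
  expect_equal(r2$weights[1] - 0.5, 0.02 * exp(-1), tolerance = 1e-12)
  expect_equal(r2$weights[2], 0.5)
  # linearity: two pre spikes add their single-spike updates
  h3 <- h
  h3 <- on_pre_spike(c(0.5, 0.5), h3, 1, 99, ltp)$hist
  h3 <- on_pre_spike(c(0.5, 0.5), h3, 1, 98, ltp)$hist
  r3 <- on_post_spike(c(0.5, 0.5), h3, 100, ltp)
  d1 <- 0.02 * exp(-1 / 20)
  d2 <- 0.02 * exp(-2 / 20)
  expect_equal(r3$weights[1] - 0.5, d1 + d2, tolerance = 1e-12)
})

test_that("pre-spike updates apply reward and respect the bounds", {
  ah <- stdp_rule("asymmetric_anti_hebbian")
  h <- spike_history(2)
  r <- on_pre_spike(c(0.1, 0.1), h, 1, 10, ah, reward_rule(0.9), TRUE)
  expect_equal(r$weights[1], 0.1 + 0.018)
  r0 <- on_pre_spike(c(0.1, 0.1), h, 1, 10, ah, reward_rule(0.9), FALSE)
  expect_equal(r0$weights[1], 0.1)
  # clipping at w_max
  r2 <- on_pre_spike(c(2, 0.1), h, 1, 10, ah, reward_rule(0.9), TRUE)
  expect_equal(r2$weights[1], 2)
  # and at w_min after strong depression
  hp <- on_post_spike(c(0.001, 0.1), h, 5, ah)$hist
  r3 <- on_pre_spike(c(0.001, 0.1), hp, 1, 5.1,
                     stdp_rule(A_post_pre = -1, A_pre_post = -1))
  expect_gte(r3$weights[1], 0)
})

test_that("history reset is idempotent and silences later updates", {
  ah <- stdp_rule("asymmetric_anti_hebbian")
  h <- spike_history(3)
  h <- on_pre_spike(rep(1, 3), h, 2, 10, ah)$hist
  expect_length(h$pre[[2]], 1)
  h1 <- reset_history(h)
  expect_identical(h1, reset_history(h1))
  expect_length(h1$pre[[2]], 0)
  r <- on_post_spike(rep(1, 3), h1, 20, ah)
  expect_equal(r$weights, rep(1, 3))
})

test_that("negating both amplitudes negates every unclipped increment", {
  set.seed(31)
  for (rep in 1:5) {
    events <- data.frame(t = sort(runif(15, 0, 50)),
                         pre = runif(15) < 0.6)
    events$ch <- ifelse(events$pre, sample(3, 15, replace = TRUE), NA)
    a <- stdp_rule(A_post_pre = 1, A_pre_post = -1)
    b <- stdp_rule(A_post_pre = -1, A_pre_post = 1)
    wa <- rep(10, 3); wb <- rep(10, 3)  # far from bounds
    ha <- spike_history(3); hb <- spike_history(3)
    for (i in seq_len(nrow(events))) {
      if (events$pre[i]) {
        ra <- on_pre_spike(wa, ha, events$ch[i], events$t[i], a,
                           w_min = -Inf, w_max = Inf)
        rb <- on_pre_spike(wb, hb, events$ch[i], events$t[i], b,
                           w_min = -Inf, w_max = Inf)
      } else {
        ra <- on_post_spike(wa, ha, events$t[i], a, w_min = -Inf, w_max = Inf)
        rb <- on_post_spike(wb, hb, events$t[i], b, w_min = -Inf, w_max = Inf)
      }
      wa <- ra$weights; ha <- ra$hist
      wb <- rb$weights; hb <- rb$hist
    }
    expect_equal(wa - 10, -(wb - 10), tolerance = 1e-12)
  }
})

test_that("weights never leave their bounds under random event sequences", {
  set.seed(77)
  for (rep in 1:10) {
    rule <- stdp_rule(A_post_pre = sample(c(-1, 1), 1),
                      A_pre_post = sample(c(-1, 1), 1),
                      epsilon = runif(1, 0.01, 0.5))
    n_ev <- 60
    tt <- sort(runif(n_ev, 0, 200))
    ch <- sample(4, n_ev, replace = TRUE)
    ext <- sort(runif(5, 0, 200))
    W0 <- runif(4, 0, 2)
    r <- simulate_trial(m1_params(), input = input_spec(ch, tt, ext),
                        weights = W0, duration = 200, noise = TRUE,
                        plasticity = rule, A_reward = runif(1, 0, 1))
    expect_true(all(r$weights >= 0 - 1e-12 & r$weights <= 2 + 1e-12))
  }
})

test_that("engine weight updates equal the history-based replay of the rule", {
  set.seed(13)
  for (rep in 1:6) {
    rule <- stdp_rule(c("symmetric_ltd", "asymmetric_hebbian",
                        "asymmetric_anti_hebbian", "symmetric_ltp")[
                          (rep %% 4) + 1])
    P <- 4
    n_ev <- 25
    tt <- sort(runif(n_ev, 0, 50))
    ch <- sample(P, n_ev, replace = TRUE)
    W0 <- runif(P, 0.05, 0.2)
    A_r <- sample(c(0, 0.9), 1)
    r <- simulate_trial(m1_params(), input = input_spec(ch, tt),
                        weights = W0, duration = 50, noise = FALSE,
                        plasticity = rule, A_reward = A_r)
    W_replay <- replay_plasticity(W0, ch, tt, r$spikes, rule, A_reward = A_r)
    expect_equal(r$weights, W_replay, tolerance = 1e-10)
  }
})

test_that("a subthreshold non-rewarded pattern never changes the weights", {
  p <- m1_params()
  pat <- four_spike_pattern(T_delay = 1)
  W <- rep(0.01, 10)
  for (i in 1:20) {
    r <- simulate_trial(p, input = as_input_spec(pat), weights = W,
                        duration = 50, noise = FALSE,
                        plasticity = stdp_rule("asymmetric_anti_hebbian"),
                        A_reward = 0)
    expect_identical(r$weights, W)
    expect_length(r$spikes, 0)
  }
})
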