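test_that("fixed-delay sequences respect the configured geometry", {
  set.seed(2)
  cfg <- task_config(P = 10, N_p = 6, N_stim = 3, t_delay = 1)
  pats <- gen_task1(cfg)
  expect_length(pats, 6)
  for (p in pats) {
    n <- length(p$times)
    expect_true(n >= 1 && n <= 3)
    expect_false(any(duplicated(p$channels)))
    expect_equal(p$times, 10 + (seq_len(n) - 1) * 1)
    expect_true(all(p$channels >= 1 & p$channels <= 10))
    expect_true(all(p$times >= 0 & p$times <= p$t_duration))
  }
  # degenerate bound: single-spike patterns only
  p1 <- gen_task1(task_config(P = 5, N_p = 3, N_stim = 1))
  expect_true(all(vapply(p1, function(p) length(p$times), 1L) == 1))
  expect_true(all(vapply(p1, function(p) p$times[1], 1) == 10))
  # patterns are distinct as channel sequences
  keys <- vapply(pats, function(p) paste(p$channels, collapse = ","), "")
  expect_false(any(duplicated(keys)))
  expect_error(gen_task1(task_config(P = 2, N_p = 10, N_stim = 2)),
               "distinct")
})

test_that("spike-count distribution over Task-1 draws is uniform on 1..N_stim", {
  set.seed(4)
  cfg <- task_config(P = 10, N_p = 1, N_stim = 3)
  counts <- table(replicate(6000, length(gen_task1(cfg)[[1]]$times)))
  expect_equal(names(counts), c("1", "2", "3"))
  # 3-sigma binomial band around 1/3
  sd3 <- 3 * sqrt(6000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - 2000) < sd3))
})

test_that("Task-1 generation is byte-reproducible under a fixed seed", {
  cfg <- task_config()
  set.seed(123); a <- gen_task1(cfg)
  set.seed(123); b <- gen_task1(cfg)
  expect_identical(a, b)
})

test_that("reward labels are independent of pattern content", {
  set.seed(6)
  cfg <- task_config(P = 10, N_p = 1, N_stim = 3)
  draws <- t(replicate(4000, {
    p <- gen_task1(cfg)[[1]]
    c(n = length(p$times), r = as.integer(p$rewarded))
  }))
  tab <- table(draws[, "n"], draws[, "r"])
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
  expect_equal(mean(draws[, "r"]), 0.5, tolerance = 0.05)
})

test_that("nested sequences enumerate channels and reward assignments", {
  n2 <- gen_task2_nested(2)
  expect_length(n2$patterns, 2)
  expect_equal(nrow(n2$assignments), 4)
  expect_equal(n2$patterns[[1]]$channels, 1L)
  expect_equal(n2$patterns[[2]]$channels, c(1L, 2L))
  expect_equal(diff(n2$patterns[[2]]$times), 0.5)
  expect_equal(nrow(gen_task2_nested(1)$assignments), 2)
  n5 <- gen_task2_nested(5)
  expect_equal(nrow(n5$assignments), 32)
  expect_equal(max(n5$patterns[[5]]$times) - min(n5$patterns[[5]]$times), 2)
})

test_that("jitter preserves content at zero and matches the stated std", {
  set.seed(8)
  base <- gen_task1(task_config(P = 10, N_p = 1, N_stim = 3,
                                t_offset = 25))[[1]]
  expect_identical(jitter_pattern(base, 0), base)
  set.seed(9); j1 <- jitter_pattern(base, 2)
  set.seed(9); j2 <- jitter_pattern(base, 2)
  expect_identical(j1, j2)
  # empirical std of shifts (away from the clipping boundary)
  one <- striatoseq:::new_pattern(1L, 25, TRUE, 25, 50)
  sh <- replicate(10000, jitter_pattern(one, 2)$times - 25)
  expect_equal(sd(sh), 2, tolerance = 0.05 * 2)
  expect_true(all(abs(sh) <= 2 * sqrt(3) + 1e-9))
  # clipping keeps times inside the trial
  wide <- replicate(200, jitter_pattern(one, 20)$times)
  expect_true(all(wide >= 0 & wide <= 50))
})

test_that("Poisson patterns have at least two spikes and the right mean count", {
  set.seed(10)
  cfg <- task_config(P = 10, N_p = 400, lambda_poisson = 1, t_poisson = 2)
  pats <- gen_task4_poisson(cfg)
  ns <- vapply(pats, function(p) length(p$times), 1L)
  expect_true(all(ns >= 2))
  expect_true(all(vapply(pats, function(p)
    all(p$times >= 10 & p$times <= 12), TRUE)))
  # conditional mean of Poisson(lambda*t) given N >= 2
  lt <- 1 * 2
  cond_mean <- (lt - lt * exp(-lt)) / (1 - exp(-lt) - lt * exp(-lt))
  expect_equal(mean(ns), cond_mean, tolerance = 0.05)
})

test_that("subpatterns are strict nonempty subsets with times preserved", {
  set.seed(12)
  p <- four_spike_pattern()
  for (i in 1:20) {
    s <- subpattern(p)
    expect_lt(length(s$times), length(p$times))
    expect_gte(length(s$times), 1)
    idx <- match(s$channels, p$channels)
    expect_false(anyNA(idx))
    expect_equal(s$times, p$times[idx])
  }
  one <- striatoseq:::new_pattern(1L, 10, TRUE, 10, 50)
  expect_error(subpattern(one), "single-spike")
})

test_that("noise merging adds the configured Poisson background", {
  p <- four_spike_pattern()
  quiet <- add_noise_spikes(p, task_config(lambda_stim = 0, lambda_ext = 0))
  expect_equal(quiet$times, p$times)
  expect_length(quiet$ext_times, 0)
  set.seed(14)
  cfg <- task_config(P = 10, lambda_stim = 1, lambda_ext = 20)
  n_extra <- replicate(3000, {
    inp <- add_noise_spikes(p, cfg)
    c(length(inp$times) - 4, length(inp$ext_times))
  })
  # lambda_stim: 1 Hz x 10 channels x 50 ms = 0.5 expected spikes
  expect_equal(mean(n_extra[1, ]), 0.5, tolerance = 0.08)
  expect_equal(mean(n_extra[2, ]), 1.0, tolerance = 0.12)
  set.seed(1); a <- add_noise_spikes(p, cfg)
  set.seed(2); b <- add_noise_spikes(p, cfg)
  expect_false(identical(a, b))
})

test_that("pattern sets round-trip through JSON", {
  set.seed(16)
  pats <- gen_task1(task_config(P = 6, N_p = 4, N_stim = 3))
  f <- withr::local_tempfile(fileext = ".json")
  patterns_to_json(pats, f)
  back <- patterns_from_json(f)
  for (k in seq_along(pats)) {
    expect_equal(back[[k]]$channels, pats[[k]]$channels)
    expect_equal(back[[k]]$times, pats[[k]]$times)
    expect_equal(back[[k]]$rewarded, pats[[k]]$rewarded)
  }
  expect_equal(attr(back, "config")$P, 6)
})
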