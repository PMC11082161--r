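#' Task configuration
#'
#' Collects the parameters defining a pattern-classification task: the size of
#' the cortical population, the pattern set, and the three noise processes
#' (background cortical spikes, external spikes onto the MSN, and timing
#' jitter).
#'
#' @param P number of cortical channels.
#' @param N_p number of patterns in the set.
#' @param N_stim maximal number of correlated spikes per pattern.
#' @param t_delay inter-spike delay within a pattern (ms); 1 for fixed-delay
#'   sequences, 0.5 for nested sequences.
#' @param tau_pattern standard deviation of per-spike timing jitter (ms).
#' @param lambda_poisson rate of the Poisson-pattern process (kHz).
#' @param t_poisson window of the Poisson-pattern process (ms).
#' @param lambda_stim background cortical spike rate per channel (Hz).
#' @param lambda_ext external (non-plastic) spike rate onto the MSN (Hz).
#' @param t_duration trial duration (ms).
#' @param t_offset start of the correlated activity (ms). No value is
#'   canonical; 10 ms leaves a wide post-pattern window inside the trial for
#'   the spike-after-the-pattern verdict.
#' @param reward_prob probability that a pattern is rewarded.
#' @return An object of class `task_config`.
#' @export
task_config <- function(P = 10, N_p = 5, N_stim = 3, t_delay = 1,
                        tau_pattern = 0, lambda_poisson = 1, t_poisson = 2,
                        lambda_stim = 0, lambda_ext = 0, t_duration = 50,
                        t_offset = 10, reward_prob = 0.5) {
  stopifnot(P >= 1, N_p >= 1, N_stim >= 1, N_stim <= P,
            t_delay >= 0, tau_pattern >= 0, lambda_poisson >= 0,
            t_poisson > 0, lambda_stim >= 0, lambda_ext >= 0,
            t_duration > 0, t_offset >= 0, t_offset < t_duration,
            reward_prob >= 0, reward_prob <= 1)
  structure(as.list(environment()), class = "task_config")
}

new_pattern <- function(channels, times, rewarded, t_offset, t_duration) {
  o <- order(times, channels)
  structure(list(channels = as.integer(channels[o]), times = times[o],
                 rewarded = isTRUE(rewarded), t_offset = t_offset,
                 t_duration = t_duration),
            class = "spike_pattern")
}

#' @export
print.spike_pattern <- function(x, ...) {
  cat(sprintf("<spike_pattern> %d spike(s), %s, t in [%g, %g] ms\n",
              length(x$times), if (x$rewarded) "rewarded" else "non-rewarded",
              x$t_offset, x$t_duration))
  if (length(x$times))
    cat(paste(sprintf("  ch %d @ %.3g ms", x$channels, x$times),
              collapse = "\n"), "\n")
  invisible(x)
}

pattern_key <- function(p) paste(p$channels, collapse = ",")

#' Fixed-delay spike sequences (Task 1)
#'
#' Draws `N_p` spatio-temporal patterns: each has `n ~ Uniform{1..N_stim}`
#' spikes on distinct channels in random order, starting at `t_offset` and
#' spaced by `t_delay`. Reward labels are i.i.d. Bernoulli(`reward_prob`),
#' independent of content. Duplicate channel sequences are rejected and
#' redrawn so that no two patterns (with possibly conflicting rewards)
#' coincide.
#'
#' @param cfg a [task_config()].
#' @return A list of `N_p` `spike_pattern`s with `cfg` attached as attribute
#'   `config`.
#' @export
gen_task1 <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$t_offset + (cfg$N_stim - 1) * cfg$t_delay > cfg$t_duration)
    stop("pattern cannot fit inside t_duration")
  seen <- character(0)
  pats <- vector("list", cfg$N_p)
  k <- 1
  guard <- 0
  while (k <= cfg$N_p) {
    n <- sample.int(cfg$N_stim, 1)
    ch <- sample.int(cfg$P, n)
    key <- paste(ch, collapse = ",")
    if (key %in% seen) {
      guard <- guard + 1
      if (guard > 10000) stop("cannot draw ", cfg$N_p, " distinct patterns")
      next
    }
    seen <- c(seen, key)
    pats[[k]] <- new_pattern(ch, cfg$t_offset + (seq_len(n) - 1) * cfg$t_delay,
                             stats::runif(1) < cfg$reward_prob,
                             cfg$t_offset, cfg$t_duration)
    k <- k + 1
  }
  attr(pats, "config") <- cfg
  pats
}

#' Nested spike sequences (Task 2)
#'
#' Builds the full family of `P` nested patterns (1), (1,2), ..., (1,...,P)
#' with `t_delay` spacing, together with the enumeration of all `2^P`
#' rewarded/non-rewarded assignments.
#'
#' @param P number of cortical channels (= number of nested patterns).
#' @param t_delay inter-spike delay (ms).
#' @param t_offset,t_duration trial geometry (ms).
#' @return list(patterns, assignments) where `assignments` is a `2^P x P`
#'   logical matrix (one row per reward assignment).
#' @export
gen_task2_nested <- function(P, t_delay = 0.5, t_offset = 10,
                             t_duration = 50) {
  stopifnot(P >= 1)
  pats <- lapply(seq_len(P), function(j)
    new_pattern(1:j, t_offset + (0:(j - 1)) * t_delay, FALSE,
                t_offset, t_duration))
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), P)))
  dimnames(grid) <- list(NULL, paste0("p", seq_len(P)))
  cfg <- task_config(P = P, N_p = P, N_stim = P, t_delay = t_delay,
                     t_duration = t_duration, t_offset = t_offset)
  attr(pats, "config") <- cfg
  list(patterns = pats, assignments = grid)
}

#' Assign rewards to a pattern set
#'
#' @param patterns a list of `spike_pattern`s.
#' @param rewarded logical vector, one flag per pattern.
#' @return The pattern list with the flags applied.
#' @export
set_rewards <- function(patterns, rewarded) {
  stopifnot(length(patterns) == length(rewarded))
  out <- mapply(function(p, r) { p$rewarded <- isTRUE(r); p },
                patterns, rewarded, SIMPLIFY = FALSE)
  attributes(out) <- attributes(patterns)
  out
}

#' Jitter the spike times of a pattern (Task 3)
#'
#' Shifts each spike by an independent uniform random variable with standard
#' deviation `tau_pattern`, i.e. Uniform(\eqn{-\tau\sqrt{3}},
#' \eqn{+\tau\sqrt{3}}). Shifted times are clipped to `[0, t_duration]`; the
#' spike order may change.
#'
#' @param p a `spike_pattern`.
#' @param tau_pattern jitter standard deviation (ms).
#' @return A jittered `spike_pattern` (a fresh realization per call).
#' @export
jitter_pattern <- function(p, tau_pattern) {
  stopifnot(inherits(p, "spike_pattern"), tau_pattern >= 0)
  if (tau_pattern == 0 || !length(p$times)) return(p)
  half <- tau_pattern * sqrt(3)
  t2 <- p$times + stats::runif(length(p$times), -half, half)
  t2 <- pmin(pmax(t2, 0), p$t_duration)
  new_pattern(p$channels, t2, p$rewarded, p$t_offset, p$t_duration)
}

#' Per-presentation jittered realizations of a pattern set (Task 3)
#'
#' @param patterns base patterns from [gen_task1()].
#' @param tau_pattern jitter standard deviation (ms); defaults to the value
#'   in the attached config.
#' @return A list of jittered `spike_pattern`s.
#' @export
gen_task3_jitter <- function(patterns, tau_pattern = NULL) {
  cfg <- attr(patterns, "config")
  if (is.null(tau_pattern)) tau_pattern <- cfg$tau_pattern
  out <- lapply(patterns, jitter_pattern, tau_pattern = tau_pattern)
  attributes(out) <- attributes(patterns)
  out
}

#' Poisson patterns (Task 4)
#'
#' Each pattern is a realization of a Poisson process of intensity
#' `lambda_poisson` (kHz) on `[t_offset, t_offset + t_poisson]`, scattered
#' uniformly over the `P` channels, rejection-sampled until the pattern holds
#' at least two spikes in total.
#'
#' @param cfg a [task_config()].
#' @return A list of `N_p` `spike_pattern`s with `cfg` attached.
#' @export
gen_task4_poisson <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  if (cfg$t_offset + cfg$t_poisson > cfg$t_duration)
    stop("Poisson window does not fit inside t_duration")
  pats <- vector("list", cfg$N_p)
  for (k in seq_len(cfg$N_p)) {
    repeat {
      n <- stats::rpois(1, cfg$lambda_poisson * cfg$t_poisson)
      if (n >= 2) break
    }
    pats[[k]] <- new_pattern(sample.int(cfg$P, n, replace = TRUE),
                             cfg$t_offset + stats::runif(n) * cfg$t_poisson,
                             stats::runif(1) < cfg$reward_prob,
                             cfg$t_offset, cfg$t_duration)
  }
  attr(pats, "config") <- cfg
  pats
}

#' Random proper subpattern
#'
#' Removes a random nonempty proper subset of a pattern's spikes, preserving
#' the times of the retained spikes. Used to probe whether a trained network
#' stays silent when only part of a learned sequence is presented.
#'
#' @param p a `spike_pattern` with at least two spikes.
#' @return A `spike_pattern` whose spike set is a strict nonempty subset of
#'   `p`'s.
#' @export
subpattern <- function(p) {
  stopifnot(inherits(p, "spike_pattern"))
  n <- length(p$times)
  if (n < 2) stop("a single-spike pattern has no proper subpattern")
  keep_n <- sample.int(n - 1, 1)
  keep <- sort(sample.int(n, keep_n))
  new_pattern(p$channels[keep], p$times[keep], p$rewarded,
              p$t_offset, p$t_duration)
}

#' Merge a pattern with background and external noise spikes
#'
#' Adds homogeneous Poisson background spikes at rate `lambda_stim` (Hz) on
#' every cortical channel and an external spike train at `lambda_ext` (Hz)
#' over `[0, t_duration]`, and returns the assembled trial input.
#'
#' @param p a `spike_pattern`.
#' @param cfg a [task_config()] providing the rates.
#' @return An [input_spec()].
#' @export
add_noise_spikes <- function(p, cfg) {
  stopifnot(inherits(p, "spike_pattern"))
  ch <- p$channels
  tt <- p$times
  if (cfg$lambda_stim > 0) {
    nbg <- stats::rpois(1, cfg$lambda_stim / 1000 * cfg$P * p$t_duration)
    if (nbg > 0) {
      ch <- c(ch, sample.int(cfg$P, nbg, replace = TRUE))
      tt <- c(tt, stats::runif(nbg) * p$t_duration)
    }
  }
  ext <- if (cfg$lambda_ext > 0) {
    next_ <- stats::rpois(1, cfg$lambda_ext / 1000 * p$t_duration)
    sort(stats::runif(next_) * p$t_duration)
  } else numeric(0)
  input_spec(channels = ch, times = tt, ext_times = ext)
}

#' Serialize a pattern set to JSON
#'
#' Writes channels, spike times, reward flags and the task configuration so
#' an experiment can be replayed exactly.
#'
#' @param patterns a list of `spike_pattern`s.
#' @param path output file path.
#' @export
patterns_to_json <- function(patterns, path) {
  cfg <- attr(patterns, "config")
  obj <- list(
    config = if (is.null(cfg)) NULL else unclass(cfg),
    patterns = lapply(patterns, function(p)
      list(channels = p$channels, times = p$times, rewarded = p$rewarded,
           t_offset = p$t_offset, t_duration = p$t_duration)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pattern set from JSON
#'
#' @param path file written by [patterns_to_json()].
#' @return A list of `spike_pattern`s (with config attribute when present).
#' @export
patterns_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  pats <- lapply(obj$patterns, function(p)
    new_pattern(p$channels, p$times, p$rewarded, p$t_offset, p$t_duration))
  if (!is.null(obj$config))
    attr(pats, "config") <- do.call(task_config, obj$config)
  pats
}
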