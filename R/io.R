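#' Default experiment configuration
#'
#' The nested configuration mirrors the simulator's structure: `task`
#' (pattern family and noise processes), `network` (neuron model, synapse
#' kernel, circuit), `plasticity` (STDP preset and reward), `training`
#' (iterations, test cadence), and optional `sweep` axes.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    task = list(id = 1, P = 10, N_p = 5, N_stim = 3, t_delay = 1,
                tau_pattern = 0, lambda_poisson = 1, t_poisson = 2,
                lambda_stim = 0, lambda_ext = 0, t_duration = 50,
                t_offset = 10, reward_prob = 0.5),
    network = list(model = "m1", kernel = "dirac", T_s = 10, n_msn = 1,
                   J = -0.5, reward_scheme = "differential",
                   w_init = c(0, 0.05), w_min = 0, w_max = 2, dt = 0.1),
    plasticity = list(rule = "asymmetric_anti_hebbian", A_post_pre = NA,
                      A_pre_post = NA, tau_stdp = 20, epsilon = 0.02,
                      A_reward = 0.9),
    training = list(n_iterations = 500, test_every = NA, T_1 = 10,
                    n_repetitions = 250, seed = 1),
    sweep = list(),
    output = list(dir = NA))
}

merge_config <- function(defaults, user, path = character(0)) {
  for (nm in names(user)) {
    here <- c(path, nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration field: ", paste(here, collapse = "$"))
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      if (!is.list(user[[nm]]))
        stop("configuration field ", paste(here, collapse = "$"),
             " must be a mapping")
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], here)
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration, checks every field against the known schema
#' (unknown fields are rejected with their full path), and fills all
#' defaults.
#'
#' @param path YAML file path.
#' @return An object of class `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user)
  structure(cfg, class = "experiment_config")
}

#' Serialize an experiment configuration to YAML
#'
#' Re-serializing a loaded configuration and loading it again is the
#' identity.
#'
#' @param cfg an `experiment_config` (or compatible list).
#' @param path output YAML path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  # polynomial rolling hash over the canonical YAML serialization
  s <- yaml::as.yaml(unclass(cfg))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

build_patterns <- function(tk) {
  cfg <- task_config(P = tk$P, N_p = tk$N_p, N_stim = tk$N_stim,
                     t_delay = tk$t_delay, tau_pattern = tk$tau_pattern,
                     lambda_poisson = tk$lambda_poisson,
                     t_poisson = tk$t_poisson, lambda_stim = tk$lambda_stim,
                     lambda_ext = tk$lambda_ext, t_duration = tk$t_duration,
                     t_offset = tk$t_offset, reward_prob = tk$reward_prob)
  switch(as.character(tk$id),
         "1" = gen_task1(cfg),
         "3" = gen_task1(cfg),  # jitter applied per presentation via cfg
         "4" = gen_task4_poisson(cfg),
         "2" = {
           nested <- gen_task2_nested(tk$P, t_delay = tk$t_delay,
                                      t_offset = tk$t_offset,
                                      t_duration = tk$t_duration)
           asg <- nested$assignments
           set_rewards(nested$patterns,
                       asg[sample.int(nrow(asg), 1), ])
         },
         stop("unknown task id: ", tk$id))
}

config_objects <- function(cfg) {
  nw <- cfg$network
  pl <- cfg$plasticity
  given <- function(x) !is.null(x) && !is.na(x)
  rule <- if (given(pl$A_post_pre) && given(pl$A_pre_post))
    stdp_rule(A_post_pre = pl$A_post_pre, A_pre_post = pl$A_pre_post,
              tau_stdp = pl$tau_stdp, epsilon = pl$epsilon)
  else stdp_rule(pl$rule, tau_stdp = pl$tau_stdp, epsilon = pl$epsilon)
  net <- network_config(model = nw$model,
                        kernel = synapse_kernel(nw$kernel, T_s = nw$T_s),
                        n_msn = nw$n_msn, J = nw$J,
                        reward_scheme = nw$reward_scheme,
                        w_init = as.numeric(nw$w_init),
                        w_min = nw$w_min, w_max = nw$w_max, dt = nw$dt)
  te <- cfg$training$test_every
  tr <- train_config(n_iterations = cfg$training$n_iterations,
                     test_every = if (given(te)) te else NULL,
                     T_1 = cfg$training$T_1,
                     n_repetitions = cfg$training$n_repetitions)
  list(rule = rule, net = net, train = tr, A_reward = pl$A_reward)
}

child_seed <- function(master, counter) {
  (as.numeric(master) * 48271 + counter * 1299709) %% 2147483647
}

#' Run a configured experiment sweep
#'
#' Runs `n_repetitions` independent trainings for every cell of the sweep
#' grid (the Cartesian product of the `sweep` axes; an empty `sweep` runs the
#' single configured cell). Each (cell, repetition) gets a deterministic
#' child seed spawned from the master seed, so results do not depend on
#' execution order. Summaries report median and quartiles of the final
#' MaxAccuracy, plus Welch t-test p-values against the first cell.
#'
#' @param cfg an `experiment_config` from [load_config()] /
#'   [default_config()].
#' @param n_repetitions overrides `cfg$training$n_repetitions` when given.
#' @return list with `results` (one row per cell x repetition), `summary`
#'   (per cell), `config_hash` and `seed`.
#' @export
run_sweep <- function(cfg, n_repetitions = NULL) {
  stopifnot(is.list(cfg))
  axes <- cfg$sweep
  grid <- if (length(axes)) do.call(expand.grid,
                                    c(axes, stringsAsFactors = FALSE))
          else data.frame(.cell = 1)
  nrep <- if (!is.null(n_repetitions)) n_repetitions
          else cfg$training$n_repetitions
  master <- cfg$training$seed
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    cell_cfg <- cfg
    if (length(axes)) {
      for (ax in names(axes)) {
        val <- grid[[ax]][ci]
        hit <- FALSE
        for (sec in c("task", "network", "plasticity", "training")) {
          if (ax %in% names(cell_cfg[[sec]])) {
            cell_cfg[[sec]][[ax]] <- val
            hit <- TRUE
            break
          }
        }
        if (!hit) stop("sweep axis not a known field: ", ax)
      }
    }
    obj <- config_objects(cell_cfg)
    for (r in seq_len(nrep)) {
      set.seed(child_seed(master, (ci - 1) * 100000 + r))
      pats <- build_patterns(cell_cfg$task)
      fit <- run_training(pats, net = obj$net, rule = obj$rule,
                          A_reward = obj$A_reward, train = obj$train)
      n <- nrow(fit$accuracy)
      row <- data.frame(cell = ci, rep = r,
                        final_accuracy = fit$accuracy$accuracy[n],
                        final_max_accuracy = fit$accuracy$max_accuracy[n])
      if (length(axes))
        for (ax in names(axes)) row[[ax]] <- grid[[ax]][ci]
      rows[[length(rows) + 1]] <- row
    }
  }
  results <- do.call(rbind, rows)
  cells <- split(results, results$cell)
  ref <- cells[[1]]$final_max_accuracy
  summary <- do.call(rbind, lapply(cells, function(g) {
    q <- stats::quantile(g$final_max_accuracy, c(0.25, 0.5, 0.75))
    p <- if (identical(g$cell[1], results$cell[1])) NA_real_
         else tryCatch(stats::t.test(g$final_max_accuracy, ref)$p.value,
                       error = function(e) NA_real_)
    out <- data.frame(cell = g$cell[1], q25 = q[[1]], median = q[[2]],
                      q75 = q[[3]], p_vs_cell1 = p)
    if (length(axes))
      for (ax in names(axes)) out[[ax]] <- g[[ax]][1]
    out
  }))
  rownames(summary) <- NULL
  list(results = results, summary = summary,
       config_hash = config_hash(cfg), seed = master)
}

#' Write sweep outputs to a directory
#'
#' Emits `results.csv`, `summary.csv` and `summary.json`; every artifact
#' embeds the configuration hash and master seed for exact replay.
#'
#' @param sweep result of [run_sweep()].
#' @param dir output directory (created if needed).
#' @export
write_sweep <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- sweep$results
  res$config_hash <- sweep$config_hash
  res$seed <- sweep$seed
  utils::write.csv(res, file.path(dir, "results.csv"), row.names = FALSE)
  utils::write.csv(cbind(sweep$summary, config_hash = sweep$config_hash,
                         seed = sweep$seed),
                   file.path(dir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(list(config_hash = sweep$config_hash,
                            seed = sweep$seed, summary = sweep$summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Write a weight trajectory as CSV
#'
#' @param weight_trace matrix (test sessions x channels) from a
#'   `striatal_fit`, or snapshots from [run_stationary_poisson()].
#' @param path output path; long format with columns `trial_index`,
#'   `channel`, `weight_nA`.
#' @export
write_weight_csv <- function(weight_trace, path) {
  wt <- as.matrix(weight_trace)
  df <- data.frame(trial_index = rep(seq_len(nrow(wt)), ncol(wt)),
                   channel = rep(seq_len(ncol(wt)), each = nrow(wt)),
                   weight_nA = as.vector(wt))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
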