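# shared fixtures: everything is generated in code at test time

default_m1 <- m1_params()
default_m2 <- m2_params()

# a fixed 4-spike template on channels 1..4 used by several theory tests
four_spike_pattern <- function(T_delay = 20 / 3, t_offset = 10,
                               t_duration = 50, rewarded = TRUE) {
  striatoseq:::new_pattern(1:4, t_offset + (0:3) * T_delay, rewarded,
                           t_offset, t_duration)
}

# short Task-1 training run used where only qualitative behaviour matters
quick_train <- function(rule = "asymmetric_anti_hebbian", A_reward = 0.9,
                        model = "m1", n_iterations = 200, N_p = 3,
                        seed = 1, n_msn = 1, J = 0) {
  set.seed(seed)
  pats <- gen_task1(task_config(P = 8, N_p = N_p, N_stim = 3))
  run_training(pats,
               net = network_config(model = model, n_msn = n_msn, J = J),
               rule = stdp_rule(rule), A_reward = A_reward,
               train = train_config(n_iterations))
}

# brute-force evaluation of the accuracy formula, independent of accuracy()
accuracy_by_hand <- function(outcomes) {
  tot <- 0
  for (i in seq_len(nrow(outcomes))) {
    r <- outcomes$rewarded[i]
    tot <- tot + if (r) as.numeric(outcomes$spiked_after[i])
                 else 1 - as.numeric(outcomes$spiked[i])
  }
  tot / nrow(outcomes)
}
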