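# Shared helpers: small random-strategy panels built in code.

random_constitutive_panel <- function(n, seed) {
  set.seed(seed)
  replicate(n, strategy_constitutive(runif(1)), simplify = FALSE)
}

random_sensing_panel <- function(n, seed) {
  set.seed(seed)
  modes <- c("nutrient_sensing", "toxin_sensing", "quorum_sensing")
  lapply(seq_len(n), function(i) {
    md <- sample(modes, 1)
    thr_max <- switch(md, nutrient_sensing = 1, toxin_sensing = 4,
                      quorum_sensing = 1.2)
    strategy_sensing(md, runif(1), runif(1), runif(1, 0, thr_max))
  })
}

# conservation functional C_A + C_B + mu_max * (T_A + T_B + N)
conserved_total <- function(traj, mu_max) {
  traj$C_A + traj$C_B + mu_max * (traj$T_A + traj$T_B + traj$N)
}
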