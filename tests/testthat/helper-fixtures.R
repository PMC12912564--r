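# Small simulation fixtures shared across test files.

# brute-force grid log-likelihood maximum for the mixture, used as an
# independent oracle against the optimiser
grid_loglik_max <- function(errors, n_pT = 101, n_kappa = 101,
                            kappa_range = c(0.1, 100)) {
  pTs <- seq(0, 1, length.out = n_pT)
  kappas <- exp(seq(log(kappa_range[1]), log(kappa_range[2]),
                    length.out = n_kappa))
  best <- -Inf
  for (k in kappas) {
    vm <- dvonmises_deg(errors, k)
    for (p in pTs) {
      ll <- sum(log(p * vm + (1 - p) / 360))
      if (ll > best) best <- ll
    }
  }
  best
}

# trial tibble for a set of subjects simulated at shared mixture parameters
make_group_trials <- function(subject_ids, group, n_trials, pT, kappa) {
  dplyr::bind_rows(lapply(subject_ids, function(id) {
    tibble::tibble(
      subject_id = id, group = group, trial = seq_len(n_trials),
      error_deg = simulate_errors(n_trials, pT, kappa)
    )
  }))
}
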