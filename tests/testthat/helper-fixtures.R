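# shared fixture builders (all generated in code; no files)

scan6 <- c(1, 10, 20, 40, 100, 200)

make_exp_tac <- function(A, lambda, times = scan6, organ = "organ",
                         units = "FIA") {
  vals <- drop(exp(-outer(times, lambda)) %*% A)
  tac(organ, times, vals, units = units, decay_corrected = TRUE)
}

# random nonnegative exponential models for oracle sweeps
random_exp_model <- function() {
  m <- sample(1:3, 1)
  list(A = stats::runif(m, 0.01, 1), lambda = stats::runif(m, 1e-4, 0.1))
}

noise_free_config <- function(seed = 1L) subject_config(seed = seed)

noisy_config <- function(seed = 1L, sigma = 0.03) {
  subject_config(pet_sigma = sigma, gamma_sigma = sigma, seed = seed)
}
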