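# Small phantom configurations used across test files; all data are
# generated in code at test time.

small_config <- function(seed = 7, ...) {
  phantom_config(dims = c(1L, 24L, 24L), seed = seed, ...)
}

# uniform acquisition grid + default gamma-variate bolus, handy for
# single-voxel kinetics tests
test_times <- function(n = 36L) seq(0, 26.9, length.out = n)

test_aif <- function(times = test_times()) {
  gamma_variate_aif(solve_gamma_params(8, 10, 3), times)
}

# brute-force pairwise concordance with ties counted 1/2 (AUC oracle)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
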