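# shorthand: a design with `nfac` binary equal-prevalence factors
bin_design <- function(n_arms = 2L, n = 200L, p = 1.0, nfac = 1L) {
  minim_design(n_arms, n, p,
               replicate(nfac, c(0.5, 0.5), simplify = FALSE))
}

# exact binomial 99% interval for an observed frequency around p0
binom_ci99 <- function(p0, n) {
  c(qbinom(0.005, n, p0), qbinom(0.995, n, p0)) / n
}

expect_freq_in_ci99 <- function(freq, p0, n) {
  ci <- binom_ci99(p0, n)
  expect_gte(freq, ci[1])
  expect_lte(freq, ci[2])
}
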