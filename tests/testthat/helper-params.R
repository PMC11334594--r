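# fitted CD34 parameter set (rates per day)
cd34_params <- function(x_max = 2e4) {
  model_params(k_on = 0.261, k_off = 19.178, d = 0.21, x_max = x_max,
               r0 = 0.426, r1 = -0.426)
}

# increasing-proliferation set used for the profile/scheme comparison figure
rising_r_params <- function(x_max = 2e4) {
  model_params(k_on = 0.85, k_off = 12.71, d = 1, x_max = x_max,
               r0 = 3.4, r1 = 3, mode = "permissive")
}

# random valid parameter sets (strict mode: r1 in [-r0, 0])
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    r0 <- stats::runif(1, 0, 3)
    model_params(k_on = stats::rlnorm(1, 0, 1),
                 k_off = stats::rlnorm(1, 1, 1),
                 d = stats::rlnorm(1, -0.5, 0.7),
                 x_max = 2e4,
                 r0 = r0, r1 = -stats::runif(1) * r0)
  })
}

# brute-force largest eigenvalue of the explicit 2x2 matrix
eigen_sM <- function(p) {
  M <- matrix(c(p$r1 - p$k_off, p$k_on, p$k_off, -p$k_on), 2, 2,
              byrow = TRUE)
  max(Re(eigen(M)$values))
}
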