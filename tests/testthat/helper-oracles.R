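# Independent analytic oracles used only by the tests.

# complex Bessel J_nu by power series (adequate for |z| up to ~15)
bessel_j_complex <- function(nu, z, terms = 60) {
  s <- 0 + 0i
  for (m in 0:terms)
    s <- s + (-1)^m * (z / 2)^(2 * m + nu) / (gamma(m + 1) * gamma(m + nu + 1))
  s
}

# Analytic pulsatile (Womersley) velocity profiles for a tube of radius R
# driven so that the cross-sectional mean velocity trace equals vm at the
# sampled phases. Returns an eta x phase matrix. The DFT convention matches
# solver snapshots taken at t_k = k T / n: reconstruction uses the sample
# index, not the shifted time stamp.
womersley_oracle <- function(vm, times, period, R, fluid, eta, n_harm = 10) {
  n <- length(vm)
  ck <- stats::fft(vm) / n
  omega <- 2 * pi / period
  nu_ <- fluid$viscosity / fluid$density
  idx <- seq_len(n) - 1
  uw <- outer(Re(ck[1]) * 2 * (1 - eta^2), rep(1, n))
  for (k in seq_len(n_harm)) {
    lam <- sqrt((1i)^3 * (k * omega) * R^2 / nu_)
    j0l <- bessel_j_complex(0, lam)
    prof <- (1 - bessel_j_complex(0, lam * eta) / j0l) /
      (1 - 2 * bessel_j_complex(1, lam) / (lam * j0l))
    uw <- uw + 2 * Re(outer(prof, exp(2i * pi * k * idx / n)) * ck[k + 1])
  }
  uw
}
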