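# Independent oracles, written from the definitions, used to cross-check the
# package implementations. These deliberately share no code with R/.

# Approximate entropy by literal template counting: for each template of
# length m, count the templates within Chebyshev distance r (self included),
# average the log fractions, and difference the two embedding dimensions.
apen_oracle <- function(u, m, r) {
  phi <- function(mm) {
    n_t <- length(u) - mm + 1
    templates <- sapply(seq_len(n_t), function(i) u[i:(i + mm - 1)])
    templates <- matrix(templates, nrow = mm)
    counts <- vapply(seq_len(n_t), function(i) {
      d <- apply(abs(templates - templates[, i]), 2, max)
      sum(d <= r)
    }, numeric(1))
    mean(log(counts / n_t))
  }
  phi(m) - phi(m + 1)
}

# SPARC by direct DFT summation (no fft call) and explicit chord summation
# over the selected band, mirroring the published adaptive-cutoff procedure.
sparc_oracle <- function(v, rate_hz, cutoff_hz = 10, amp_th = 0.05,
                         nfft = NULL) {
  n <- length(v)
  if (is.null(nfft)) nfft <- 2^ceiling(log2(4 * n))
  vp <- c(v, rep(0, nfft - n))
  half <- floor(nfft / 2) + 1
  k <- 0:(half - 1)
  idx <- 0:(nfft - 1)
  mag <- vapply(k, function(kk)
    Mod(sum(vp * exp(-2i * pi * kk * idx / nfft))), numeric(1))
  freq <- k * rate_hz / nfft
  mag <- mag / max(mag)
  sel <- which(freq <= min(cutoff_hz, rate_hz / 2))
  f <- freq[sel]; m <- mag[sel]
  above <- which(m >= amp_th)
  keep <- above[1]:above[length(above)]
  f <- f[keep]; m <- m[keep]
  fr <- f[length(f)] - f[1]
  arc <- 0
  for (i in seq_len(length(f) - 1))
    arc <- arc + sqrt(((f[i + 1] - f[i]) / fr)^2 + (m[i + 1] - m[i])^2)
  -arc
}

# exact two-sided permutation p for Spearman's rho by brute enumeration,
# generated with a different algorithm (recursive insertion) than the
# implementation uses
spearman_perm_oracle <- function(xs, ys) {
  n <- length(xs)
  all_perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (p in all_perms(v[-length(v)])) {
      for (pos in 0:length(p)) {
        out[[length(out) + 1]] <- append(p, v[length(v)], after = pos)
      }
    }
    out
  }
  rho_obs <- cor(xs, ys, method = "spearman")
  rhos <- vapply(all_perms(seq_len(n)),
                 function(p) cor(xs, ys[p], method = "spearman"), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# single-frequency discrete Fourier amplitude, for resampling fidelity checks
fft_amplitude_at <- function(v, rate_hz, f_target) {
  n <- length(v)
  freq <- (0:(n - 1)) * rate_hz / n
  a <- Mod(fft(v)) / n * 2
  a[which.min(abs(freq - f_target))]
}

# a minimal uniform trajectory for unit tests
make_traj <- function(y, x = NULL, rate_hz = 15, trial_id = "test") {
  n <- length(y)
  if (is.null(x)) x <- rep(1.5, n)
  paw_trajectory((0:(n - 1)) / rate_hz, x, y, trial_id = trial_id,
                 rate_hz = rate_hz)
}
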