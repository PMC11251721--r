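# Independent statistical oracles, coded from the textbook formulas with a
# different numerical route (complex resultants) than the package.

ww_oracle <- function(groups) {
  z <- lapply(groups, function(g) exp(1i * g * pi / 180))
  ns <- lengths(groups); N <- sum(ns); k <- length(groups)
  Ri <- vapply(z, function(v) Mod(sum(v)), numeric(1))
  R <- Mod(sum(unlist(z)))
  rw <- sum(Ri) / N
  kap <- if (rw < 0.53) 2 * rw + rw^3 + 5 * rw^5 / 6
         else if (rw < 0.85) -0.4 + 1.39 * rw + 0.43 / (1 - rw)
         else 1 / (rw^3 - 4 * rw^2 + 3 * rw)
  Fs <- (1 + 3 / (8 * kap)) * ((N - k) * (sum(Ri) - R)) /
    ((k - 1) * (N - sum(Ri)))
  list(F = Fs, p = pf(Fs, k - 1, N - k, lower.tail = FALSE))
}
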