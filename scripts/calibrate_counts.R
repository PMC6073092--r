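# One-off calibration of the percents-per-abstract distribution used by
# generator_config(): X = 1 + NegBin(size, mu), searched on a grid so the
# theoretical quartiles of X are exactly (2, 3, 6) — median 3, IQR 2-6.
# Result hard-coded in generator_config(nb_size = 1.2, nb_mu = 3.5).
hits <- NULL
for (size in seq(0.6, 3, by = 0.2)) {
  for (mu in seq(2, 5, by = 0.25)) {
    q <- 1 + qnbinom(c(0.25, 0.5, 0.75), size = size, mu = mu)
    if (all(q == c(2, 3, 6))) {
      hits <- rbind(hits, data.frame(size = size, mu = mu))
    }
  }
}
print(hits)  # (1.2, 3.5) chosen: central among the admissible pairs
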