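# Independent brute-force oracles used to freeze expected values.

# median with midpoint convention, written against sorted order statistics
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

# per-column median absolute deviation by enumeration
oracle_mad <- function(X) {
  apply(as.matrix(X), 2L, function(x) oracle_median(abs(x - oracle_median(x))))
}

# closed-form conversion-reaction solution x2(t) from x0 = (1, 0)
oracle_conversion_x2 <- function(theta, t) {
  s <- theta[1] + theta[2]
  theta[1] / s * (1 - exp(-s * t))
}

# simulate a matrix of draws, one problem simulator call per row
sim_matrix <- function(problem, Theta) {
  t(vapply(seq_len(nrow(Theta)),
           function(i) problem$simulator(Theta[i, ]),
           numeric(problem$n_y)))
}
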