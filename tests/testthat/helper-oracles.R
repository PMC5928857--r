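# Independent brute-force / closed-form oracles used across the suite.
# Each is deliberately naive and shares no code with the package internals.

# all mutation-spanning substrings of the given lengths, by direct looping
oracle_enumerate <- function(window_seq, offset, lengths) {
  out <- character()
  W <- nchar(window_seq)
  for (L in lengths) {
    if (L > W) next
    for (s in seq_len(W - L + 1)) {
      if (s <= offset && s + L - 1 >= offset) {
        out <- c(out, substr(window_seq, s, s + L - 1))
      }
    }
  }
  unique(paste(out, nchar(out)))
}

# two-tailed Fisher p by full hypergeometric enumeration over tables with
# the observed margins (probability-mass rule)
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(k) {
    choose(r1, k) * choose(r2, c1 - k) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[match(a, a_range)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# chi-square statistic for a 2x2 table, textbook formula (no correction)
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; co <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + co + d
  n * (a * d - b * co)^2 /
    ((a + b) * (co + d) * (a + co) * (b + d))
}

# product-limit estimator by explicit event-time looping
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    died <- sum(time == tt[i] & event == 1)
    s <- s * (1 - died / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, survival = surv)
}

# two-group log-rank chi-square by observed-vs-expected accumulation
oracle_logrank <- function(time, event, group) {
  g <- unique(group)
  tt <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t0 in tt) {
    n <- sum(time >= t0)
    n1 <- sum(time >= t0 & group == g[1])
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == g[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# AUC by brute-force pair counting with half credit for ties
oracle_auc <- function(scores, outcome) {
  pos <- scores[outcome]
  neg <- scores[!outcome]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# small planted cohort reused by several tests
tiny_cohort <- function(seed = 11, ...) {
  simulate_cohort(sim_config(
    n_samples = 12, cells_per_sample = 150, n_genes = 200,
    n_signature_genes = 30, n_mutations_per_patient = 8,
    detect_prob = 1, seed = seed, ...))
}
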