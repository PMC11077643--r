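# Independent brute-force oracles used to verify the implementations.
# These are deliberately naive, position-by-position / pair-by-pair
# computations, kept separate from the package code paths they check.

# ssGSEA by explicit position-by-position running-sum enumeration.
oracle_ssgsea <- function(profile, gene_set, alpha_w, normalize) {
  ord <- order(-profile, names(profile))
  genes <- names(profile)[ord]
  n <- length(genes)
  in_set <- genes %in% gene_set
  rank_weight <- rev(seq_len(n))          # N .. 1 down the ranking
  denom_in <- sum(rank_weight[in_set]^alpha_w)
  n_out <- n - sum(in_set)
  total <- 0
  p_in <- 0; p_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + rank_weight[i]^alpha_w / denom_in
    else p_out <- p_out + 1 / n_out
    total <- total + (p_in - p_out)
  }
  if (normalize) total / n else total
}

# ROC-AUC by exhaustive pair counting.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "FIN"); neg <- which(labels == "AIN")
  conc <- 0; tied <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) conc <- conc + 1
    else if (scores[i] == scores[j]) tied <- tied + 1
  }
  (conc + 0.5 * tied) / (length(pos) * length(neg))
}

# BH step-up by the definitional formula q_(i) = min_{j>=i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Two-sample moderated t computed step by step (scalar loops), following
# the log-variance method-of-moments prior fit.
oracle_moderated_t <- function(m, g1, g2) {
  n1 <- length(g1); n2 <- length(g2); d <- n1 + n2 - 2
  lfc <- s2 <- numeric(nrow(m))
  for (g in seq_len(nrow(m))) {
    x1 <- m[g, g1]; x2 <- m[g, g2]
    lfc[g] <- mean(x1) - mean(x2)
    s2[g] <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / d
  }
  s2 <- pmax(s2, .Machine$double.eps)
  e <- log(s2) - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (evar <= 0) {
    d0 <- Inf; s02 <- exp(mean(e))
    s2post <- rep(s02, length(s2))
  } else {
    # invert trigamma by uniroot, independently of the package's Newton step
    d0 <- 2 * uniroot(function(y) trigamma(y) - evar,
                      c(1e-4, 1e8), tol = 1e-12)$root
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    s2post <- (d0 * s02 + d * s2) / (d0 + d)
  }
  tt <- lfc / sqrt(s2post * (1 / n1 + 1 / n2))
  list(lfc = lfc, t = tt, df = d + d0,
       p = 2 * pt(-abs(tt), d + d0))
}

# Kaplan-Meier by a hand lifetable over distinct times.
oracle_km <- function(times, events) {
  s <- 1
  out <- NULL
  for (tt in sort(unique(times))) {
    at_risk <- sum(times >= tt)
    d <- sum(times == tt & events == 1)
    cns <- sum(times == tt & events == 0)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, c(time = tt, n_risk = at_risk, n_event = d,
                        n_censor = cns, surv = s))
  }
  as.data.frame(out)
}

# Two-group log-rank by explicit O-E / hypergeometric-variance sums.
oracle_logrank <- function(times, events, groups) {
  gl <- sort(unique(groups))
  o_minus_e <- 0; v <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at <- times >= tt
    n <- sum(at)
    n1 <- sum(at & groups == gl[1])
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & groups == gl[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  o_minus_e^2 / v
}
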