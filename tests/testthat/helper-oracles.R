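# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition (pair enumeration, explicit
# risk sets, hypergeometric sums) rather than reusing any package code path.

# AUC by explicit enumeration of all (positive, negative) pairs.
brute_force_auc <- function(scores, labels, positive = "MSI") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Breslow partial log-likelihood for a single covariate.
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Cox score test statistic at beta = 0 (Breslow risk sets). With no tied
# event times and a binary covariate this equals the log-rank statistic.
cox_score_statistic <- function(time, event, x) {
  u <- 0
  v <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    xbar <- mean(x[risk])
    u <- u + x[i] - xbar
    v <- v + mean(x[risk]^2) - xbar^2
  }
  u^2 / v
}

# Two-sided Fisher p by direct hypergeometric enumeration over the support,
# minimum-likelihood rule (R's fisher.test convention, incl. its relative
# tolerance for probability ties).
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  min(1, sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)]))
}

# Small random expression cohort for oracle checks.
random_cohort <- function(n_genes = 10, n_msi = 4, n_mss = 4) {
  n <- n_msi + n_mss
  m <- matrix(rnorm(n_genes * n), n_genes, n,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n))))
  expression_cohort(m, c(rep("MSI", n_msi), rep("MSS", n_mss)))
}
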