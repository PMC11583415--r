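# Independent brute-force oracles and small fixture builders used across the
# suite. The oracles enumerate null distributions directly and never call the
# implementation paths they check.

# Exhaustive two-sided Mann-Whitney p-value: enumerate every assignment of
# the pooled values to the two groups and count assignments whose U is at
# least as far from the null mean as the observed U (the U distribution is
# symmetric under exchangeability without ties).
brute_force_mw_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  N <- length(pooled)
  u_for <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - m * (m + 1) / 2
  }
  u_obs <- u_for(seq_len(m))
  mu <- m * (N - m) / 2
  combs <- utils::combn(N, m)
  us <- apply(combs, 2, u_for)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Exhaustive two-sided Fisher p-value by the probability-mass rule: sum the
# hypergeometric probabilities of every table with the observed margins whose
# probability does not exceed the observed table's (within the classic 1e-7
# relative tolerance).
brute_force_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  N <- a + b + c + d
  lo <- max(0, c1 - (N - r1))
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, N - r1, c1)
  p_obs <- stats::dhyper(a, r1, N - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up Benjamini-Hochberg computed literally from the definition.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Two-group log-rank chi-square from first principles: observed minus
# expected events in group 1 over the risk sets at each event time, with the
# hypergeometric variance.
brute_force_logrank_chisq <- function(times, events, group1) {
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# A small dependency panel fast enough for unit tests: 60 lines x 60 genes,
# 12 LOF lines, two planted co-essential partners and four planted SL
# partners.
tiny_panel_config <- function(...) {
  args <- list(
    n_lines = 60, n_genes = 60, n_lof_lines = 12, missing_rate = 0.02,
    planted_coessential = data.frame(gene_a = "G0001",
                                     gene_b = c("G0002", "G0003"),
                                     rho = c(0.85, -0.85)),
    planted_gi = data.frame(query_gene = "G0001",
                            partner_gene = sprintf("G%04d", 30:33),
                            lof_mean = 0.85, wt_mean = 0.15)
  )
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}

# Term collection with k_true groups of identical sets, disjoint between
# groups (between-group Jaccard index 0).
planted_term_collection <- function(k_true, terms_per_group = 4,
                                    genes_per_set = 12) {
  sets <- list()
  for (g in seq_len(k_true)) {
    core <- sprintf("C%d_%02d", g, seq_len(genes_per_set))
    for (t in seq_len(terms_per_group)) {
      sets[[sprintf("T%d_%d", g, t)]] <- core
    }
  }
  gene_set_collection(sets)
}
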