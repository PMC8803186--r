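# Fixture generators and independent oracles shared across the suite.

# random normalized two-group dataset; integer values make ties likely
random_normalized <- function(n1 = sample(3:6, 1), n2 = sample(3:6, 1),
                              censor_prob = 0.3, tie_pool = 8) {
  v <- sample(seq_len(tie_pool), n1 + n2, replace = TRUE)
  phi <- stats::rbinom(n1 + n2, 1, 1 - censor_prob)
  if (sum(phi) == 0) phi[sample(n1 + n2, 1)] <- 1L
  new_normalized(v[1:n1], v[-(1:n1)], phi[1:n1], phi[-(1:n1)])
}

# random raw Cq table with a normalizer row per sample
random_cq_tibble <- function(n_samples = 10, n_targets = 4, undet_prob = 0.2) {
  targets <- c("norm", sprintf("m%d", seq_len(n_targets)))
  rows <- expand.grid(sample_id = sprintf("S%02d", seq_len(n_samples)),
                      target_id = targets, stringsAsFactors = FALSE)
  undet <- rows$target_id != "norm" & stats::runif(nrow(rows)) < undet_prob
  tibble::tibble(
    sample_id = rows$sample_id,
    group_label = ifelse(as.integer(sub("S", "", rows$sample_id)) <= n_samples / 2,
                         "control", "treated"),
    target_id = rows$target_id,
    cq = ifelse(undet, NA_real_, round(stats::runif(nrow(rows), 18, 39), 2)),
    is_determined = !undet
  )
}

# Naive full-enumeration oracle for the exact test: rebuilds the risk table
# (counts, expectations, pooled KM weights) from scratch for every labeling.
# Deliberately loop-based and independent of the package's score shortcut.
oracle_exact_pvalue <- function(value, phi, n1, fh_p = 0, fh_q = 0,
                                alternative = "two_sided", tol = 1e-10) {
  n <- length(value)
  labelings <- utils::combn(n, n1)
  stat_for <- function(g1_idx) {
    grp <- rep(2L, n)
    grp[g1_idx] <- 1L
    ev <- sort(unique(value[phi == 1]))
    u <- 0
    s <- 1
    for (d in ev) {
      at <- value >= d
      p <- sum(at)
      p1 <- sum(at & grp == 1L)
      o <- sum(value == d & phi == 1)
      o1 <- sum(value == d & phi == 1 & grp == 1L)
      w <- s^fh_p * (1 - s)^fh_q
      u <- u + w * (o1 - p1 * o / p)
      s <- s * (1 - o / p)
    }
    u
  }
  stats_all <- apply(labelings, 2, stat_for)
  t_obs <- stat_for(seq_len(n1))
  mu <- mean(stats_all)
  switch(alternative,
    two_sided = mean(abs(stats_all - mu) >= abs(t_obs - mu) - tol),
    rate1_greater = mean(stats_all >= t_obs - tol),
    rate1_less = mean(stats_all <= t_obs + tol)
  )
}

# brute-force hypergeometric moments from the pmf written with binomial
# coefficients (no calls to dhyper)
hyper_moments_brute <- function(p1, p2, o) {
  p <- p1 + p2
  k <- max(0, o - p2):min(o, p1)
  pmf <- choose(o, k) * choose(p - o, p1 - k) / choose(p, p1)
  m <- sum(k * pmf)
  list(mean = m, var = sum((k - m)^2 * pmf))
}
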