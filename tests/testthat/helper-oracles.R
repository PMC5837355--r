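# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: generic lm()/solve() fits, direct evaluation of
# definitions, and brute-force enumeration.

# origin-constrained WLS slope via lm()
oracle_wls_origin <- function(g, G, w) {
  fit <- lm(G ~ 0 + g, weights = w)
  list(beta = unname(coef(fit)[1]),
       se = sqrt(1 / sum(w * g^2)))
}

# two-regressor origin-constrained WLS via lm(); SEs from normal equations
oracle_wls_two <- function(g1, g2, G, w) {
  fit <- lm(G ~ 0 + g1 + g2, weights = w)
  X <- cbind(g1, g2)
  list(beta = unname(coef(fit)),
       se = unname(sqrt(diag(solve(t(X) %*% (w * X))))))
}

# WLS with intercept via lm(); sigma-scaled SEs
oracle_wls_intercept <- function(g, G, w) {
  fit <- lm(G ~ g, weights = w)
  sm <- summary(fit)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = sm$coefficients[1, 2] * sqrt((length(g) - 2) /
                                                     (length(g) - 2)),
       se_slope = sm$coefficients[2, 2])
}

# direct evaluation of the interpolated weighted-quantile definition
oracle_weighted_quantile <- function(b, w, q = 0.5) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (q <= s[1]) return(b[1])
  if (q >= s[length(s)]) return(b[length(b)])
  i <- max(which(s <= q))
  b[i] + (b[i + 1] - b[i]) * (q - s[i]) / (s[i + 1] - s[i])
}

# brute-force validation of a pruning result: no retained pair at/above the
# threshold, and every removed variant conflicts with a retained variant of
# better (smaller p, ties lexical) rank
oracle_prune_valid <- function(kept, all_snps, pvals, r2mat, thr) {
  names(pvals) <- all_snps
  rank_of <- rank(order(order(pvals, all_snps)))
  for (a in kept) for (b in kept) {
    if (a != b && r2mat[a, b] >= thr) return(FALSE)
  }
  removed <- setdiff(all_snps, kept)
  for (r in removed) {
    better <- kept[r2mat[r, kept] >= thr]
    ok <- any(vapply(better, function(k) {
      pvals[k] < pvals[r] || (pvals[k] == pvals[r] && k < r)
    }, logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}

# quick harmonized-set builder around random draws
random_hset <- function(k, beta = 0.3, seed = 1, se_G = 0.05) {
  set.seed(seed)
  g <- rnorm(k, 0.1, 0.05)
  sG <- abs(rnorm(k, se_G, se_G / 4)) + 0.01
  G <- beta * g + rnorm(k, 0, sG)
  harmonized_set(gamma = g, se_gamma = rep(0.01, k), Gamma = G,
                 se_Gamma = sG)
}
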