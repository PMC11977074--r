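# Independent brute-force oracles used to freeze expected values.

# nearest neighbour by linear scan over the (sorted) support; ties take the
# first (= smaller) element
brute_snap <- function(x, v) {
  v <- sort(v)
  vapply(x, function(xi) v[which.min(abs(v - xi))], numeric(1))
}

# means over ALL ordered I-tuples of scale values (expand.grid enumeration);
# the multiset enumeration must reproduce exactly this set of distinct means
brute_possible_means <- function(vals, I, tol = 1e-9) {
  g <- as.matrix(do.call(expand.grid, rep(list(vals), I)))
  m <- sort(rowMeans(g))
  m[c(TRUE, diff(m) > tol)]
}

# two-sided p-value from the t CDF via the incomplete beta function,
# independent of pt()
p_from_beta <- function(t, df) {
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

random_composition <- function(D, kappa) {
  p <- stats::rgamma(D, shape = 1.5) + 1e-3
  composition(kappa * p / sum(p), kappa)
}
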