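# brute-force enumeration helpers (oracles, independent of the package)

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

perm_pvalue_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  stats <- vapply(all_perms(ry), function(p) abs(cor(rx, p)), numeric(1))
  mean(stats >= obs - 1e-9)
}

signrank_pvalue_oracle <- function(d) {
  # exact two-sided p by enumerating every sign pattern of |d| ranks
  r <- rank(abs(d))
  n <- length(d)
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

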