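# Exact posterior over membership vectors for small instances, by direct
# enumeration of all K^J assignments. Collapses beta and psi analytically:
# the stick-breaking prior contributes prod_{k<K} B(1+n_k, alpha+s_k)/B(1,alpha)
# (n_k = occupancy, s_k = individuals in later groups) and each group's counts
# contribute their Dirichlet-multinomial marginal (multinomial coefficients
# are constant across assignments and drop out of the normalisation).
exact_z_posterior <- function(w, K, alpha, eps) {
  J <- nrow(w)
  L <- ncol(w)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), J)))
  lp <- apply(grid, 1L, function(z) {
    n_k <- tabulate(z, K)
    s_k <- rev(cumsum(rev(n_k))) - n_k
    out <- sum(lbeta(1 + n_k[-K], alpha + s_k[-K]) - lbeta(1, alpha))
    for (k in seq_len(K)) {
      c_k <- colSums(w[z == k, , drop = FALSE])
      out <- out + lgamma(L * eps) - lgamma(L * eps + sum(c_k)) +
        sum(lgamma(eps + c_k) - lgamma(eps))
    }
    out
  })
  p <- exp(lp - max(lp))
  list(grid = grid, p = p / sum(p))
}

# empirical distribution of a chain's membership vectors on the oracle grid
empirical_z_distribution <- function(z_draws, grid) {
  keys <- apply(grid, 1L, paste, collapse = "")
  emp <- table(factor(apply(z_draws, 1L, paste, collapse = ""), levels = keys))
  as.numeric(emp) / nrow(z_draws)
}

tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# every count matrix with J <= 3 rows over L = 1..2 locations and row totals
# of 3, up to reordering of rows (the membership-vector distribution is
# equivariant under row permutations)
oracle_instances <- function() {
  insts <- list(matrix(3L, 1, 1), matrix(3L, 2, 1), matrix(3L, 3, 1))
  rows2 <- list(c(3L, 0L), c(2L, 1L), c(1L, 2L), c(0L, 3L))
  for (J in 1:3) {
    gr <- as.matrix(expand.grid(rep(list(seq_along(rows2)), J)))
    keys <- apply(gr, 1L, function(r) paste(sort(r), collapse = ""))
    gr <- gr[!duplicated(keys), , drop = FALSE]
    for (i in seq_len(nrow(gr))) {
      insts[[length(insts) + 1L]] <- do.call(rbind, rows2[gr[i, ]])
    }
  }
  insts
}
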