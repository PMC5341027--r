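#' Model hyperparameters
#'
#' The mixture has three hyperparameters: the truncation level `K` (maximum
#' number of groups; the model prunes unused groups, so `K` only needs to be
#' comfortably larger than the number of groups actually supported by the
#' data), the stick-breaking concentration `alpha` (smaller values favour
#' fewer occupied groups), and the symmetric Dirichlet concentration
#' `epsilon` placed on each group's visitation profile (small values make
#' this prior vague). Defaults are K = 25, alpha = 0.1, epsilon = 0.1.
#'
#' @param K positive integer, maximum number of groups.
#' @param alpha positive real, concentration of the Beta(1, alpha) sticks.
#' @param epsilon positive real, per-location Dirichlet concentration.
#' @return a list of class `ibc_hyper`.
#' @export
ibc_hyper <- function(K = 25L, alpha = 0.1, epsilon = 0.1) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L) stop("K must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  structure(list(K = K, alpha = alpha, epsilon = epsilon), class = "ibc_hyper")
}

#' Group probabilities from stick fractions
#'
#' Truncated stick-breaking construction: given stick fractions
#' `V_1, ..., V_K` with `V_K = 1`, the probability of group k is
#' `beta_k = V_k * prod_{m<k} (1 - V_m)`. Because the last stick is 1 the
#' result is an exact probability simplex over the K groups.
#'
#' @param V numeric vector of stick fractions in `[0, 1]`, last element
#'   exactly 1.
#' @return numeric vector `beta` summing to 1.
#' @examples
#' stick_breaking_weights(c(0.5, 0.5, 1))  # 0.5, 0.25, 0.25
#' @export
stick_breaking_weights <- function(V) {
  if (!is.numeric(V) || length(V) < 1L) stop("V must be a nonempty numeric vector", call. = FALSE)
  if (any(V < 0 | V > 1)) stop("stick fractions must lie in [0, 1]", call. = FALSE)
  if (V[length(V)] != 1) stop("the last stick fraction must be exactly 1", call. = FALSE)
  K <- length(V)
  remain <- cumprod(c(1, 1 - V[-K]))
  V * remain
}

#' Stick state (V and derived beta)
#'
#' @param V stick fractions, last element 1.
#' @return list of class `ibc_sticks` with elements `V` and `beta`.
#' @export
sticks_state <- function(V) {
  beta <- stick_breaking_weights(V)
  structure(list(V = as.numeric(V), beta = beta), class = "ibc_sticks")
}

#' Posterior group-membership probabilities for one individual
#'
#' Full conditional of the membership indicator given the group weights and
#' profiles: `p_k` is proportional to `beta_k * prod_l psi[k, l]^w_j[l]`,
#' evaluated in log space with max-subtraction so that large counts do not
#' underflow.
#'
#' @param w_j integer vector of location counts for one individual.
#' @param beta group-probability simplex (length K).
#' @param psi K x L matrix of visitation profiles, rows on the simplex.
#' @return probability vector over the K groups.
#' @export
assignment_probabilities <- function(w_j, beta, psi) {
  psi <- as.matrix(psi)
  if (length(w_j) != ncol(psi)) stop("w_j length must equal ncol(psi)", call. = FALSE)
  if (length(beta) != nrow(psi)) stop("beta length must equal nrow(psi)", call. = FALSE)
  lp <- log(beta)
  nz <- which(w_j > 0)
  if (length(nz) > 0L) {
    lp <- lp + as.numeric(log(psi[, nz, drop = FALSE]) %*% w_j[nz])
  }
  m <- max(lp)
  if (!is.finite(m)) {
    stop("all group log-probabilities are -Inf; check that psi is positive where counts are positive",
         call. = FALSE)
  }
  p <- exp(lp - m)
  p / sum(p)
}

#' Gibbs update: draw group memberships
#'
#' Each individual's group indicator is drawn independently from its full
#' conditional [assignment_probabilities()]. Uses R's global RNG stream.
#'
#' @param counts an [count_matrix()] object.
#' @param sticks an `ibc_sticks` state (or a bare `beta` simplex).
#' @param profiles K x L profile matrix.
#' @return integer vector of group indices, one per individual.
#' @export
sample_assignments <- function(counts, sticks, profiles) {
  stopifnot(inherits(counts, "ibc_counts"))
  beta <- if (inherits(sticks, "ibc_sticks")) sticks$beta else as.numeric(sticks)
  psi <- as.matrix(profiles)
  if (ncol(counts) != ncol(psi)) stop("counts and profiles disagree on the number of locations", call. = FALSE)
  if (length(beta) != nrow(psi)) stop("beta and profiles disagree on the number of groups", call. = FALSE)
  vapply(seq_len(nrow(counts)), function(j) {
    p <- assignment_probabilities(unclass(counts)[j, ], beta, psi)
    sample.int(length(p), 1L, prob = p)
  }, integer(1L))
}

#' Gibbs update: draw stick fractions given memberships
#'
#' Conjugate update of the truncated stick-breaking prior. With group
#' occupancies `n_k` and tail sums `s_k = sum_{m>k} n_m`, each stick is drawn
#' as `V_k ~ Beta(1 + n_k, alpha + s_k)` for k < K, and `V_K = 1`.
#'
#' @param z integer vector of group memberships.
#' @param hyper an [ibc_hyper()] object.
#' @return an `ibc_sticks` state.
#' @export
sample_sticks <- function(z, hyper) {
  stopifnot(inherits(hyper, "ibc_hyper"))
  K <- hyper$K
  if (any(z < 1L | z > K)) stop("memberships out of range 1..K", call. = FALSE)
  n_k <- tabulate(z, nbins = K)
  s_k <- rev(cumsum(rev(n_k))) - n_k  # individuals in groups after k
  V <- numeric(K)
  if (K > 1L) {
    V[seq_len(K - 1L)] <- stats::rbeta(K - 1L, 1 + n_k[-K], hyper$alpha + s_k[-K])
  }
  V[K] <- 1
  sticks_state(V)
}

#' Gibbs update: draw visitation profiles given memberships
#'
#' Conjugate Dirichlet update: row k is drawn from
#' `Dirichlet(epsilon + c_k1, ..., epsilon + c_kL)` where `c_kl` is the total
#' count at location l over the individuals currently in group k. Groups with
#' no members draw from the `Dirichlet(epsilon, ..., epsilon)` prior.
#'
#' @param counts an [count_matrix()] object.
#' @param z integer memberships.
#' @param hyper an [ibc_hyper()] object.
#' @return K x L matrix with rows on the simplex, columns named by location.
#' @export
sample_profiles <- function(counts, z, hyper) {
  stopifnot(inherits(counts, "ibc_counts"), inherits(hyper, "ibc_hyper"))
  K <- hyper$K
  L <- ncol(counts)
  if (length(z) != nrow(counts)) stop("z length must match the number of individuals", call. = FALSE)
  c_kl <- matrix(0, K, L)
  w <- unclass(counts)
  for (k in seq_len(K)) {
    rows <- which(z == k)
    if (length(rows) > 0L) c_kl[k, ] <- colSums(w[rows, , drop = FALSE])
  }
  g <- matrix(stats::rgamma(K * L, shape = hyper$epsilon + c_kl), K, L)
  psi <- g / rowSums(g)
  colnames(psi) <- colnames(counts)
  psi
}

#' Observed-data log-likelihood of the mixture
#'
#' Sum over individuals of the log mixture likelihood
#' `log sum_k beta_k * Multinomial(w_j; n_j, psi_k)`, including the
#' multinomial coefficients (constant in the parameters, so conditionals are
#' unaffected; it is included so that traces are comparable across runs).
#' Evaluated in log space.
#'
#' @param counts an [count_matrix()] object.
#' @param sticks an `ibc_sticks` state or a bare `beta` simplex.
#' @param profiles K x L profile matrix.
#' @return a scalar log-likelihood.
#' @export
log_likelihood <- function(counts, sticks, profiles) {
  stopifnot(inherits(counts, "ibc_counts"))
  beta <- if (inherits(sticks, "ibc_sticks")) sticks$beta else as.numeric(sticks)
  psi <- as.matrix(profiles)
  w <- unclass(counts)
  n_j <- rowSums(w)
  log_coef <- lgamma(n_j + 1) - rowSums(lgamma(w + 1))
  lp <- w %*% t(log(psi))                       # J x K
  lp <- sweep(lp, 2L, log(beta), "+")
  m <- apply(lp, 1L, max)
  sum(log_coef + m + log(rowSums(exp(lp - m))))
}
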