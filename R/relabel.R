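#' Resolve label switching in stored mixture draws
#'
#' A mixture posterior is invariant to permuting group indices, so per-group
#' summaries are meaningless until draws share a common labeling. Two passes
#' are applied. Within each draw, groups are re-indexed in decreasing order
#' of occupancy `n_k` (ties keep the original index order), so group 1 is
#' always the largest in that draw. Across draws, each draw's groups are then
#' greedily matched to the running mean profile matrix by smallest total
#' variation distance between `psi` rows: the globally closest (group, slot)
#' pair is matched first, both are removed, and so on. Memberships `z`,
#' weights `beta`, and profiles `psi` are permuted together; stick fractions
#' `V` are recomputed from the permuted `beta`.
#'
#' @param samples an `ibc_samples` object.
#' @return an `ibc_samples` object with `relabeled = TRUE`.
#' @export
relabel_samples <- function(samples) {
  stopifnot(inherits(samples, "ibc_samples"))
  nd <- n_draws(samples)
  if (nd == 0L) stop("no stored draws to relabel", call. = FALSE)
  K <- samples$hyper$K
  J <- ncol(samples$z)
  if (K == 1L) {
    samples$relabeled <- TRUE
    return(samples)
  }

  z <- samples$z
  beta <- samples$beta
  psi <- samples$psi
  run_mean <- NULL
  run_occ <- NULL

  for (d in seq_len(nd)) {
    psi_d <- matrix(psi[d, , ], K, dim(psi)[3L])

    # pass 1: occupancy order (stable sort breaks ties by original index)
    n_k <- tabulate(z[d, ], nbins = K)
    perm <- order(-n_k)
    # pass 2: greedy match to the running mean by total variation distance;
    # an occupancy-fraction term keeps the matching stable when profiles are
    # nearly indistinguishable (e.g. empty groups drawn from the same prior)
    if (!is.null(run_mean)) {
      cand <- psi_d[perm, , drop = FALSE]
      occ_cand <- n_k[perm] / J
      D <- 0.5 * .rowwise_l1(cand, run_mean) +
        abs(outer(occ_cand, run_occ, "-"))     # K x K: draw-group x slot
      match_perm <- integer(K)
      free_rows <- rep(TRUE, K)
      free_cols <- rep(TRUE, K)
      for (step in seq_len(K)) {
        Dm <- D
        Dm[!free_rows, ] <- Inf
        Dm[, !free_cols] <- Inf
        idx <- arrayInd(which.min(Dm), dim(Dm))
        match_perm[idx[2L]] <- idx[1L]
        free_rows[idx[1L]] <- FALSE
        free_cols[idx[2L]] <- FALSE
      }
      perm <- perm[match_perm]
    }

    inv <- integer(K)
    inv[perm] <- seq_len(K)
    z[d, ] <- inv[z[d, ]]
    beta[d, ] <- beta[d, perm]
    psi_d <- psi_d[perm, , drop = FALSE]
    psi[d, , ] <- psi_d

    occ_d <- tabulate(z[d, ], nbins = K) / J
    if (is.null(run_mean)) {
      run_mean <- psi_d
      run_occ <- occ_d
    } else {
      run_mean <- (run_mean * (d - 1) + psi_d) / d
      run_occ <- (run_occ * (d - 1) + occ_d) / d
    }
  }

  samples$z <- z
  colnames(samples$z) <- samples$row_labels
  samples$beta <- beta
  samples$psi <- psi
  dimnames(samples$psi) <- list(NULL, NULL, samples$col_labels)
  samples$V <- .sticks_from_beta(beta)
  samples$relabeled <- TRUE
  samples
}

# pairwise L1 distances between rows of A and rows of B (both K x L)
.rowwise_l1 <- function(A, B) {
  K <- nrow(A)
  D <- matrix(0, K, nrow(B))
  for (i in seq_len(K)) {
    D[i, ] <- colSums(abs(t(B) - A[i, ]))
  }
  D
}

# invert the stick-breaking map row-wise: V_k = beta_k / (1 - sum_{m<k} beta_m)
.sticks_from_beta <- function(beta) {
  K <- ncol(beta)
  V <- matrix(0, nrow(beta), K)
  for (d in seq_len(nrow(beta))) {
    remain <- 1
    for (k in seq_len(K - 1L)) {
      V[d, k] <- if (remain > 0) min(1, beta[d, k] / remain) else 0
      remain <- remain - beta[d, k]
    }
    V[d, K] <- 1
  }
  V
}
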