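#' Fit the individual-based clustering model by blocked Gibbs sampling
#'
#' Clusters individuals by their location-visitation counts under a
#' multinomial mixture. Group weights carry a truncated stick-breaking prior
#' (`V_k ~ Beta(1, alpha)`, `V_K = 1`, `beta_k = V_k prod_{m<k}(1 - V_m)`)
#' that favours few occupied groups, so the number of groups is learned up to
#' the truncation level K; each group's visitation profile `psi_k` carries a
#' symmetric `Dirichlet(epsilon)` prior.
#'
#' Each sweep draws, in order, the profiles `psi | z`, the sticks
#' `V, beta | z` (both conjugate), and the memberships `z | beta, psi`
#' (independent categorical draws in log space). Memberships are initialised
#' uniformly at random over the K groups. The per-sweep observed-data
#' log-likelihood (multinomial coefficients included) is recorded for chain
#' monitoring. Runs are fully reproducible from `seed`.
#'
#' @param counts an [count_matrix()] object (individuals x locations).
#' @param hyper an [ibc_hyper()] object; defaults to K = 25,
#'   alpha = 0.1, epsilon = 0.1.
#' @param n_iter total sweeps; must exceed `burnin`.
#' @param burnin sweeps discarded from the front of the chain.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed for the run.
#' @param z_init optional integer vector of starting memberships (length J);
#'   by default drawn uniformly from the seeded generator.
#' @return an object of class `ibc_samples`: a list with `z` (draws x J
#'   integer matrix), `beta` and `V` (draws x K), `psi` (draws x K x L
#'   array), `loglik` (length `n_iter`), the schedule, hyperparameters,
#'   seed, and row/column labels.
#' @seealso [conditional_refit()] to re-estimate profiles on later data with
#'   memberships frozen; [relabel_samples()] before per-group summaries.
#' @examples
#' sim <- simulate_counts(scenario_preset("scenario1", n_per_group = 10), seed = 1)
#' fit <- run_gibbs(sim$counts, n_iter = 200, burnin = 100, thin = 2, seed = 1)
#' @export
run_gibbs <- function(counts, hyper = ibc_hyper(), n_iter = 10000L,
                      burnin = 5000L, thin = 10L, seed = 1L, z_init = NULL) {
  stopifnot(inherits(counts, "ibc_counts"), inherits(hyper, "ibc_hyper"))
  .check_schedule(n_iter, burnin, thin)
  set.seed(seed)
  J <- nrow(counts)
  if (is.null(z_init)) {
    z_init <- sample.int(hyper$K, J, replace = TRUE)
  } else {
    z_init <- as.integer(z_init)
    if (length(z_init) != J || any(z_init < 1L | z_init > hyper$K)) {
      stop("z_init must be length J with entries in 1..K", call. = FALSE)
    }
  }
  raw <- gibbs_cpp(unclass(counts), hyper$K, hyper$alpha, hyper$epsilon,
                   as.integer(n_iter), as.integer(burnin), as.integer(thin),
                   z_init, TRUE, TRUE, numeric(0))
  .as_samples(raw, counts, hyper, n_iter, burnin, thin, seed,
              z_fixed = FALSE, relabeled = FALSE)
}

#' Re-estimate visitation profiles for a later period with memberships frozen
#'
#' The device used for temporal change detection: individuals keep the group
#' membership learned from an earlier window, and only the visitation
#' profiles `psi` (and, by default, the group weights `beta`) are re-drawn
#' from the later window's counts. Differences between the two windows'
#' `psi` posteriors then measure how the same set of individuals shifted
#' their visitation (see [delta_visitation()]).
#'
#' Rows of `counts_new` are matched to `z_fixed` by individual ID;
#' individuals missing from the later window are dropped with a warning, as
#' are later-window individuals with no known membership. Groups left with no
#' members revert to the `Dirichlet(epsilon)` prior.
#'
#' @param counts_new an [count_matrix()] for the later window.
#' @param z_fixed named integer vector of memberships (names = individual
#'   IDs), e.g. [posterior_modes()] of an earlier fit.
#' @param hyper,n_iter,burnin,thin,seed as in [run_gibbs()].
#' @param resample_beta if `FALSE`, the group weights stay frozen at
#'   `beta_fixed` instead of being re-drawn (period-specific weights are the
#'   default).
#' @param beta_fixed simplex of length K, required when
#'   `resample_beta = FALSE`.
#' @return an `ibc_samples` object whose `z` draws all equal the frozen
#'   memberships.
#' @export
conditional_refit <- function(counts_new, z_fixed, hyper = ibc_hyper(),
                              n_iter = 10000L, burnin = 5000L, thin = 10L,
                              seed = 1L, resample_beta = TRUE,
                              beta_fixed = NULL) {
  stopifnot(inherits(counts_new, "ibc_counts"), inherits(hyper, "ibc_hyper"))
  .check_schedule(n_iter, burnin, thin)
  if (is.null(names(z_fixed))) {
    if (length(z_fixed) != nrow(counts_new)) {
      stop("unnamed z_fixed must have one entry per row of counts_new", call. = FALSE)
    }
    names(z_fixed) <- rownames(counts_new)
  }
  keep <- intersect(rownames(counts_new), names(z_fixed))
  if (length(keep) == 0L) {
    stop("no overlap between counts_new individuals and z_fixed names", call. = FALSE)
  }
  n_drop_z <- sum(!names(z_fixed) %in% keep)
  n_drop_w <- sum(!rownames(counts_new) %in% keep)
  if (n_drop_z > 0L) {
    warning(sprintf("%d individual(s) with known membership absent from the new counts; dropped",
                    n_drop_z), call. = FALSE)
  }
  if (n_drop_w > 0L) {
    warning(sprintf("%d individual(s) in the new counts have no known membership; dropped",
                    n_drop_w), call. = FALSE)
  }
  w <- count_matrix(unclass(counts_new)[keep, , drop = FALSE],
                    row_labels = keep, col_labels = colnames(counts_new))
  z <- as.integer(z_fixed[keep])
  if (any(z < 1L | z > hyper$K)) stop("z_fixed entries out of range 1..K", call. = FALSE)
  if (!resample_beta) {
    if (is.null(beta_fixed) || length(beta_fixed) != hyper$K) {
      stop("resample_beta = FALSE requires beta_fixed of length K", call. = FALSE)
    }
  } else {
    beta_fixed <- numeric(0)
  }
  set.seed(seed)
  raw <- gibbs_cpp(unclass(w), hyper$K, hyper$alpha, hyper$epsilon,
                   as.integer(n_iter), as.integer(burnin), as.integer(thin),
                   z, FALSE, resample_beta, as.numeric(beta_fixed))
  .as_samples(raw, w, hyper, n_iter, burnin, thin, seed,
              z_fixed = TRUE, relabeled = TRUE)
}

.check_schedule <- function(n_iter, burnin, thin) {
  if (!(n_iter > burnin && burnin >= 0L && thin >= 1L)) {
    stop("need n_iter > burnin >= 0 and thin >= 1", call. = FALSE)
  }
  if ((n_iter - burnin) < thin) stop("schedule keeps zero draws", call. = FALSE)
  invisible(NULL)
}

.as_samples <- function(raw, counts, hyper, n_iter, burnin, thin, seed,
                        z_fixed, relabeled) {
  out <- list(
    z = raw$z, beta = raw$beta, V = raw$V, psi = raw$psi,
    loglik = raw$loglik,
    n_iter = as.integer(n_iter), burnin = as.integer(burnin),
    thin = as.integer(thin), seed = as.integer(seed),
    hyper = hyper,
    row_labels = rownames(counts), col_labels = colnames(counts),
    z_fixed = isTRUE(z_fixed), relabeled = isTRUE(relabeled)
  )
  colnames(out$z) <- out$row_labels
  dimnames(out$psi) <- list(NULL, NULL, out$col_labels)
  class(out) <- "ibc_samples"
  out
}

#' @export
print.ibc_samples <- function(x, ...) {
  cat(sprintf(
    "IBC posterior samples: %d kept draws (n_iter %d, burnin %d, thin %d), %d individuals, %d locations, K = %d%s%s\n",
    nrow(x$z), x$n_iter, x$burnin, x$thin, length(x$row_labels),
    length(x$col_labels), x$hyper$K,
    if (x$z_fixed) ", memberships frozen" else "",
    if (x$relabeled) ", relabeled" else ""
  ))
  occ <- colMeans(x$beta)
  cat(sprintf("posterior mean beta (top 5): %s\n",
              paste(sprintf("%.3f", sort(occ, decreasing = TRUE)[1:min(5, length(occ))]),
                    collapse = ", ")))
  invisible(x)
}

#' Number of kept posterior draws
#' @param samples an `ibc_samples` object.
#' @return integer draw count.
#' @export
n_draws <- function(samples) {
  stopifnot(inherits(samples, "ibc_samples"))
  nrow(samples$z)
}

#' Posterior-mode group membership per individual
#'
#' The most frequent group index across kept draws, per individual (ties to
#' the lowest index). Run [relabel_samples()] first so that group indices are
#' comparable across draws.
#'
#' @param samples an `ibc_samples` object.
#' @return named integer vector (names = individual IDs).
#' @export
posterior_modes <- function(samples) {
  stopifnot(inherits(samples, "ibc_samples"))
  K <- samples$hyper$K
  modes <- apply(samples$z, 2L, function(col) which.max(tabulate(col, nbins = K)))
  names(modes) <- samples$row_labels
  modes
}

#' Posterior mean of the visitation profiles
#' @param samples an `ibc_samples` object.
#' @return K x L matrix, columns named by location.
#' @export
psi_mean <- function(samples) {
  stopifnot(inherits(samples, "ibc_samples"))
  m <- apply(samples$psi, c(2L, 3L), mean)
  colnames(m) <- samples$col_labels
  m
}

#' Posterior mean of the group weights
#' @param samples an `ibc_samples` object.
#' @return numeric simplex of length K.
#' @export
beta_mean <- function(samples) {
  stopifnot(inherits(samples, "ibc_samples"))
  colMeans(samples$beta)
}

#' Write posterior samples as long-format delimited text plus a manifest
#'
#' One file per parameter block (`<prefix>_z.csv`, `<prefix>_beta.csv`,
#' `<prefix>_psi.csv`, `<prefix>_loglik.csv`; columns draw / group /
#' location / value as applicable) and `<prefix>_manifest.json` recording
#' hyperparameters, schedule, seed, and software version.
#'
#' @param samples an `ibc_samples` object.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_samples <- function(samples, prefix) {
  stopifnot(inherits(samples, "ibc_samples"))
  nd <- n_draws(samples)
  K <- samples$hyper$K
  L <- length(samples$col_labels)
  files <- character(0)

  f <- paste0(prefix, "_z.csv")
  utils::write.csv(data.frame(
    draw = rep(seq_len(nd), times = ncol(samples$z)),
    individual = rep(samples$row_labels, each = nd),
    group = as.vector(samples$z)
  ), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- paste0(prefix, "_beta.csv")
  utils::write.csv(data.frame(
    draw = rep(seq_len(nd), times = K),
    group = rep(seq_len(K), each = nd),
    value = as.vector(samples$beta)
  ), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- paste0(prefix, "_psi.csv")
  utils::write.csv(data.frame(
    draw = rep(seq_len(nd), times = K * L),
    group = rep(rep(seq_len(K), each = nd), times = L),
    location = rep(samples$col_labels, each = nd * K),
    value = as.vector(samples$psi)
  ), f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- paste0(prefix, "_loglik.csv")
  utils::write.csv(data.frame(iteration = seq_along(samples$loglik),
                              loglik = samples$loglik),
                   f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  f <- paste0(prefix, "_manifest.json")
  jsonlite::write_json(list(
    K = samples$hyper$K, alpha = samples$hyper$alpha,
    epsilon = samples$hyper$epsilon,
    n_iter = samples$n_iter, burnin = samples$burnin, thin = samples$thin,
    seed = samples$seed, z_fixed = samples$z_fixed,
    relabeled = samples$relabeled,
    version = as.character(utils::packageVersion("ibclust"))
  ), f, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, f)

  invisible(files)
}
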