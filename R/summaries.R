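#' Effective groups and their posterior summaries
#'
#' The stick-breaking prior leaves most of the K potential groups empty, so
#' only a handful of "effective" groups carry individuals. A group is
#' effective when its posterior mean occupancy fraction (average share of
#' individuals assigned to it across kept draws) reaches `min_share`.
#'
#' @param samples a relabeled `ibc_samples` object (see
#'   [relabel_samples()]).
#' @param min_share minimum posterior mean occupancy fraction in `[0, 1)`;
#'   the default 0.01 drops groups holding under 1% of individuals.
#' @return data.frame with one row per effective group (ordered by
#'   decreasing occupancy): `group`, `occupancy` (posterior mean fraction of
#'   individuals), `beta_mean` (posterior mean prior weight), `n_members`
#'   (members at the posterior mode). The total fraction of individuals
#'   covered by the retained groups is in `attr(, "coverage")`, and the
#'   posterior-mode member IDs per group in `attr(, "members")`.
#' @export
effective_groups <- function(samples, min_share = 0.01) {
  stopifnot(inherits(samples, "ibc_samples"))
  if (n_draws(samples) == 0L) stop("no stored draws", call. = FALSE)
  if (min_share < 0 || min_share >= 1) stop("min_share must lie in [0, 1)", call. = FALSE)
  if (!samples$relabeled) {
    warning("samples are not relabeled; per-group summaries may mix labels", call. = FALSE)
  }
  K <- samples$hyper$K
  J <- ncol(samples$z)
  occ <- rowMeans(apply(samples$z, 1L, tabulate, nbins = K)) / J
  bm <- beta_mean(samples)
  keep <- which(occ >= min_share & occ > 0)
  keep <- keep[order(-occ[keep], keep)]
  modes <- posterior_modes(samples)
  members <- lapply(keep, function(k) names(modes)[modes == k])
  out <- data.frame(group = keep, occupancy = occ[keep], beta_mean = bm[keep],
                    n_members = lengths(members), row.names = NULL)
  attr(out, "coverage") <- sum(occ[keep])
  attr(out, "members") <- stats::setNames(members, keep)
  out
}

#' Classify locations as unvisited, single-group, or mixed-membership
#'
#' A location is `mixed` when its posterior mean visitation rate exceeds
#' `cutoff` for two or more effective groups, `single` when exactly one group
#' clears the cutoff, and `unvisited` otherwise. Mixed locations are the
#' critical connectivity sites: places through which multiple groups are
#' linked.
#'
#' @param psi_mean K x L posterior mean profile matrix (see [psi_mean()]).
#' @param groups integer indices of the effective groups to consider.
#' @param cutoff visitation-rate cutoff in `[0, 1)`; default 0.02.
#' @return data.frame with `location`, `status` (factor:
#'   unvisited/single/mixed), `n_groups`, and a list column `groups` of the
#'   visiting group indices.
#' @export
mixed_membership_sites <- function(psi_mean, groups, cutoff = 0.02) {
  psi <- as.matrix(psi_mean)
  if (length(groups) == 0L) stop("empty effective-group list", call. = FALSE)
  if (any(groups < 1L | groups > nrow(psi))) stop("group index out of range", call. = FALSE)
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)", call. = FALSE)
  sub <- psi[groups, , drop = FALSE]
  above <- sub > cutoff
  n_vis <- colSums(above)
  status <- factor(ifelse(n_vis >= 2L, "mixed",
                          ifelse(n_vis == 1L, "single", "unvisited")),
                   levels = c("unvisited", "single", "mixed"))
  labs <- colnames(psi)
  if (is.null(labs)) labs <- sprintf("L%02d", seq_len(ncol(psi)))
  out <- data.frame(location = labs, status = status, n_groups = as.integer(n_vis),
                    row.names = NULL)
  out$groups <- lapply(seq_len(ncol(psi)), function(l) groups[above[, l]])
  out
}

#' Within-group location links above a visitation cutoff
#'
#' For one group, links every unordered pair of locations whose posterior
#' mean visitation rates both exceed `cutoff` — the clique over that group's
#' above-cutoff sites, i.e. the connectivity the group induces among its
#' sites. Default cutoff 0.05.
#'
#' @param psi_mean K x L posterior mean profile matrix.
#' @param group a single group index.
#' @param cutoff visitation-rate cutoff in `[0, 1)`.
#' @return data.frame with `from`, `to` (location labels, from < to in site
#'   order), `group`, `cutoff`; zero rows when fewer than two sites clear the
#'   cutoff.
#' @export
group_edges <- function(psi_mean, group, cutoff = 0.05) {
  psi <- as.matrix(psi_mean)
  if (length(group) != 1L || group < 1L || group > nrow(psi)) {
    stop(sprintf("unknown group index %s (profiles have %d rows)",
                 paste(group, collapse = ","), nrow(psi)), call. = FALSE)
  }
  if (cutoff < 0 || cutoff >= 1) stop("cutoff must lie in [0, 1)", call. = FALSE)
  labs <- colnames(psi)
  if (is.null(labs)) labs <- sprintf("L%02d", seq_len(ncol(psi)))
  sites <- which(psi[group, ] > cutoff)
  if (length(sites) < 2L) {
    return(data.frame(from = character(0), to = character(0),
                      group = integer(0), cutoff = numeric(0)))
  }
  pairs <- utils::combn(sites, 2L)
  data.frame(from = labs[pairs[1L, ]], to = labs[pairs[2L, ]],
             group = as.integer(group), cutoff = cutoff, row.names = NULL)
}

#' Temporal change in visitation with credible-interval significance
#'
#' Compares two windows' visitation-profile posteriors for the same groups:
#' for each (group, location), forms posterior draws of
#' `delta = psi_t2 - psi_t1`, the posterior mean, an equal-tailed credible
#' interval from empirical percentiles, and a significance flag set when the
#' interval excludes 0. `samples_t2` is normally a [conditional_refit()] with
#' the first window's memberships frozen, so group labels line up by
#' construction. Draws are paired by index when both chains keep the same
#' number of draws; otherwise draws are resampled independently with the
#' current RNG stream (which widens intervals slightly).
#'
#' @param samples_t1,samples_t2 `ibc_samples` for the two windows; location
#'   labels must match.
#' @param level credible level in (0, 1); default 0.95.
#' @param groups group indices to report (default: all K).
#' @param site_roles optional character vector of length L annotating each
#'   location (e.g. "invaded"/"non-invaded").
#' @return data.frame with `group`, `location`, `mean`, `lower`, `upper`,
#'   `significant`, and `role` when `site_roles` is given.
#' @export
delta_visitation <- function(samples_t1, samples_t2, level = 0.95,
                             groups = NULL, site_roles = NULL) {
  stopifnot(inherits(samples_t1, "ibc_samples"), inherits(samples_t2, "ibc_samples"))
  if (!identical(samples_t1$col_labels, samples_t2$col_labels)) {
    stop("location labels differ between the two sample sets", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  K <- samples_t1$hyper$K
  if (samples_t2$hyper$K != K) stop("sample sets disagree on K", call. = FALSE)
  if (is.null(groups)) groups <- seq_len(K)
  L <- length(samples_t1$col_labels)
  if (!is.null(site_roles) && length(site_roles) != L) {
    stop("site_roles must have one entry per location", call. = FALSE)
  }
  n1 <- n_draws(samples_t1)
  n2 <- n_draws(samples_t2)
  if (n1 == n2) {
    i1 <- seq_len(n1)
    i2 <- i1
  } else {
    n <- max(n1, n2)
    i1 <- sample.int(n1, n, replace = TRUE)
    i2 <- sample.int(n2, n, replace = TRUE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  res <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    k <- groups[gi]
    d <- samples_t2$psi[i2, k, , drop = FALSE] - samples_t1$psi[i1, k, , drop = FALSE]
    d <- matrix(d, length(i1), L)
    qs <- apply(d, 2L, stats::quantile, probs = probs, names = FALSE, type = 7)
    res[[gi]] <- data.frame(
      group = as.integer(k), location = samples_t1$col_labels,
      mean = colMeans(d), lower = qs[1L, ], upper = qs[2L, ],
      row.names = NULL
    )
  }
  out <- do.call(rbind, res)
  out$significant <- out$lower > 0 | out$upper < 0
  if (!is.null(site_roles)) {
    out$role <- rep(site_roles, times = length(groups))
  }
  out
}

#' Estimate origin shares from location "ownership"
#'
#' For each requested location l, finds the effective group that visits l the
#' most (`k* = argmax_k psi_mean[k, l]`) and reports that group's posterior
#' mean weight as the share of individuals originating from l. Ties go to the
#' lowest group index (with a message).
#'
#' @param psi_mean K x L posterior mean profile matrix with location column
#'   names.
#' @param beta_mean posterior mean group-weight simplex of length K.
#' @param locations character vector of location labels to report.
#' @param groups effective group indices to search over (default: all K).
#' @return data.frame with `location`, `group` (k*), `share` (beta of k*),
#'   `psi` (k*'s visitation rate at l).
#' @export
origin_shares <- function(psi_mean, beta_mean, locations, groups = NULL) {
  psi <- as.matrix(psi_mean)
  if (length(beta_mean) != nrow(psi)) stop("beta_mean length must equal nrow(psi_mean)", call. = FALSE)
  labs <- colnames(psi)
  if (is.null(labs)) labs <- sprintf("L%02d", seq_len(ncol(psi)))
  missing_loc <- setdiff(locations, labs)
  if (length(missing_loc) > 0L) {
    stop(sprintf("unknown location label(s): %s", paste(missing_loc, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(groups)) groups <- seq_len(nrow(psi))
  out <- data.frame(location = locations, group = NA_integer_,
                    share = NA_real_, psi = NA_real_, row.names = NULL)
  for (i in seq_along(locations)) {
    col <- psi[groups, labs == locations[i]]
    best <- which(col == max(col))
    if (length(best) > 1L) {
      message(sprintf("tie for the top visitor of %s; keeping the lowest group index",
                      locations[i]))
    }
    k_star <- groups[min(best)]
    out$group[i] <- k_star
    out$share[i] <- beta_mean[k_star]
    out$psi[i] <- psi[k_star, labs == locations[i]]
  }
  out
}

#' Distribution of an individual-level attribute within each group
#'
#' Cross-tabulates a per-individual attribute (e.g. year of birth, origin)
#' against group membership — information that was never shown to the model,
#' so systematic differences between groups indicate that movement groups
#' align with the attribute.
#'
#' @param assignments named integer vector of group memberships (e.g.
#'   [posterior_modes()]).
#' @param attribute named vector (categorical or numeric) aligned to
#'   individuals by name.
#' @param groups group indices to report (default: all present).
#' @return for a categorical attribute, a data.frame of `group`, `value`,
#'   `n`, `fraction` (fractions sum to 1 within each group); for a numeric
#'   attribute, a data.frame of per-group five-number summaries
#'   (`min`, `q1`, `median`, `q3`, `max`) plus `n`.
#' @export
cohort_composition <- function(assignments, attribute, groups = NULL) {
  if (is.null(names(assignments)) || is.null(names(attribute))) {
    stop("assignments and attribute must both be named by individual ID", call. = FALSE)
  }
  common <- intersect(names(assignments), names(attribute))
  if (length(common) == 0L) {
    stop("no individuals shared between assignments and attribute", call. = FALSE)
  }
  z <- assignments[common]
  a <- attribute[common]
  if (is.null(groups)) groups <- sort(unique(as.integer(z)))
  if (is.numeric(a)) {
    res <- lapply(groups, function(k) {
      v <- a[z == k]
      fn <- stats::fivenum(v)
      data.frame(group = k, n = length(v), min = fn[1], q1 = fn[2],
                 median = fn[3], q3 = fn[4], max = fn[5])
    })
    return(do.call(rbind, res))
  }
  a <- as.character(a)
  res <- lapply(groups, function(k) {
    v <- a[z == k]
    if (length(v) == 0L) return(NULL)
    tab <- table(v)
    data.frame(group = k, value = names(tab), n = as.integer(tab),
               fraction = as.numeric(tab) / length(v), row.names = NULL)
  })
  do.call(rbind, res)
}
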