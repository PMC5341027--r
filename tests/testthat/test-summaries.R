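# small fitted object shared across blocks: clean two-group data
.fit_two_groups <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      psi <- rbind(rep(c(0.25, 0), c(4, 4)), rep(c(0, 0.25), c(4, 4)))
      spec <- scenario_spec(psi, group_sizes = c(30L, 10L), effort = 15L,
                            label = "two-groups")
      sim <- simulate_counts(spec, seed = 21)
      fit <- relabel_samples(run_gibbs(sim$counts, ibc_hyper(K = 10L),
                                       n_iter = 1500L, burnin = 500L,
                                       thin = 2L, seed = 21))
      val <<- list(fit = fit, sim = sim)
    }
    val
  }
})

test_that("effective groups reflect posterior occupancy and coverage", {
  fs <- .fit_two_groups()
  eg <- effective_groups(fs$fit, min_share = 0.01)
  expect_equal(nrow(eg), 2L)
  expect_equal(eg$occupancy, c(0.75, 0.25), tolerance = 0.05)
  expect_equal(attr(eg, "coverage"), 1, tolerance = 0.02)
  expect_equal(sum(eg$n_members), 40L)
  # min_share = 0 returns every occupied group, full coverage
  eg0 <- effective_groups(fs$fit, min_share = 0)
  expect_equal(attr(eg0, "coverage"), 1, tolerance = 1e-9)
  expect_error(effective_groups(fs$fit, min_share = 1), "min_share")
})

test_that("single-group data collapses to one effective group", {
  w <- count_matrix(matrix(c(rep(5L, 50L), rep(0L, 50L)), 50L, 2L))
  fit <- relabel_samples(run_gibbs(w, n_iter = 2000L, burnin = 1000L,
                                   thin = 2L, seed = 5))
  eg <- effective_groups(fit, min_share = 0.01)
  expect_equal(nrow(eg), 1L)
  expect_equal(attr(eg, "coverage"), 1, tolerance = 0.05)
})

test_that("site classification separates unvisited, single, and mixed", {
  psi <- rbind(c(0.5, 0.3, 0.2, 0), c(0, 0, 0.3, 0.7))
  cls <- mixed_membership_sites(psi, groups = 1:2, cutoff = 0.02)
  expect_equal(as.character(cls$status), c("single", "single", "mixed", "single"))
  expect_equal(cls$groups[[3L]], 1:2)
  # orthogonal profiles never produce mixed sites at a positive cutoff
  orth <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  expect_false(any(mixed_membership_sites(orth, 1:2, 0.01)$status == "mixed"))
  # a cutoff above every entry leaves everything unvisited
  expect_true(all(mixed_membership_sites(psi, 1:2, 0.9)$status == "unvisited"))
  # raising the cutoff never promotes single to mixed
  for (cut in c(0, 0.1, 0.25, 0.4)) {
    lo <- mixed_membership_sites(psi, 1:2, cut)
    hi <- mixed_membership_sites(psi, 1:2, min(cut + 0.2, 0.99))
    promoted <- lo$status == "single" & hi$status == "mixed"
    expect_false(any(promoted))
  }
  expect_error(mixed_membership_sites(psi, integer(0)), "empty")
})

test_that("group edge lists are cliques over above-cutoff sites", {
  psi <- rbind(c(0.3, 0.3, 0.3, 0.05, 0.05), c(0.96, 0.01, 0.01, 0.01, 0.01))
  e <- group_edges(psi, 1L, cutoff = 0.05)
  expect_equal(nrow(e), 3L)                      # C(3, 2)
  expect_true(all(e$from < e$to))
  expect_equal(nrow(group_edges(psi, 2L, cutoff = 0.05)), 0L)
  # monotonicity: edges at a higher cutoff are a subset
  e02 <- group_edges(psi, 1L, cutoff = 0.02)
  key <- function(d) paste(d$from, d$to)
  expect_true(all(key(e) %in% key(e02)))
  expect_error(group_edges(psi, 7L), "unknown group")
})

test_that("identical sample sets produce zero deltas and no significance", {
  fs <- .fit_two_groups()
  d <- delta_visitation(fs$fit, fs$fit, groups = 1:2)
  expect_true(all(d$mean == 0))
  expect_true(all(d$lower == 0 & d$upper == 0))
  expect_false(any(d$significant))
})

test_that("credible intervals nest and flags match interval exclusion", {
  fs <- .fit_two_groups()
  # perturb a copy so deltas are nonzero: shift one group's profiles
  shifted <- fs$fit
  shifted$psi[, 1L, ] <- shifted$psi[, 1L, , drop = FALSE] * 0.5
  shifted$psi[, 1L, 1L] <- shifted$psi[, 1L, 1L] + 0.5 * 1  # renormalise-ish
  d95 <- delta_visitation(fs$fit, shifted, level = 0.95, groups = 1:2)
  d50 <- delta_visitation(fs$fit, shifted, level = 0.50, groups = 1:2)
  expect_true(all(d50$lower >= d95$lower - 1e-12))
  expect_true(all(d50$upper <= d95$upper + 1e-12))
  expect_true(all(d95$lower <= d95$mean & d95$mean <= d95$upper))
  expect_equal(d95$significant, d95$lower > 0 | d95$upper < 0)
  # site annotation is carried through
  roles <- rep(c("invaded", "other"), c(2L, 6L))
  da <- delta_visitation(fs$fit, shifted, groups = 1L, site_roles = roles)
  expect_equal(da$role, roles)
  bad <- fs$fit
  bad$col_labels <- rev(bad$col_labels)
  expect_error(delta_visitation(fs$fit, bad), "location labels")
})

test_that("origin shares look up the top-visiting group's weight", {
  psi <- rbind(c(0.8, 0.2, 0), c(0, 0.1, 0.9))
  colnames(psi) <- c("A", "B", "C")
  os <- origin_shares(psi, c(0.7, 0.3), c("A", "B", "C"))
  expect_equal(os$group, c(1L, 1L, 2L))
  expect_equal(os$share, c(0.7, 0.7, 0.3))
  expect_equal(os$psi, c(0.8, 0.2, 0.9))
  # ties resolve to the lowest group index, with a message
  tie <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  colnames(tie) <- c("A", "B")
  expect_message(ost <- origin_shares(tie, c(0.6, 0.4), "A"), "tie")
  expect_equal(ost$group, 1L)
  expect_error(origin_shares(psi, c(0.7, 0.3), "nowhere"), "nowhere")
})

test_that("origin shares recover true group proportions on home-location data", {
  # each group concentrates 0.8 of its mass on its own home location
  psi <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1), c(0.1, 0.1, 0.8))
  spec <- scenario_spec(psi, group_sizes = c(60L, 30L, 10L), effort = 25L,
                        label = "homes")
  sim <- simulate_counts(spec, seed = 31)
  fit <- relabel_samples(run_gibbs(sim$counts, ibc_hyper(K = 10L),
                                   n_iter = 2000L, burnin = 1000L,
                                   thin = 2L, seed = 31))
  eg <- effective_groups(fit)
  os <- origin_shares(psi_mean(fit), beta_mean(fit),
                      fit$col_labels, groups = eg$group)
  true_share <- c(0.6, 0.3, 0.1)
  expect_true(all(abs(sort(os$share, decreasing = TRUE) - true_share) < 0.05))
})

test_that("cohort composition tabulates attributes the model never saw", {
  fs <- .fit_two_groups()
  z <- posterior_modes(fs$fit)
  # constant attribute: every group is 100% that value
  const <- setNames(rep("x", length(z)), names(z))
  cc <- cohort_composition(z, const)
  expect_true(all(cc$fraction == 1))
  # attribute equal to the true group: composition is diagonal
  truth <- setNames(as.character(fs$sim$true_assignments),
                    names(fs$sim$true_assignments))
  cc2 <- cohort_composition(z, truth)
  top <- do.call(rbind, lapply(split(cc2, cc2$group),
                               function(d) d[which.max(d$fraction), ]))
  expect_true(all(top$fraction > 0.95))
  # numeric attribute: five-number summary per group
  yob <- setNames(2000 + (fs$sim$true_assignments == 2L) * 10 +
                    seq_along(z) %% 3, names(z))
  cn <- cohort_composition(z, yob)
  expect_true(all(c("median", "q1", "q3") %in% names(cn)))
  expect_error(cohort_composition(unname(z), const), "named")
  expect_error(cohort_composition(z, setNames(1, "ghost")), "no individuals")
})

test_that("a correlated binary attribute is recovered at its design rate", {
  fs <- .fit_two_groups()
  sim <- fs$sim
  set.seed(41)
  flip <- runif(length(sim$true_assignments)) < 0.9
  attr_val <- ifelse(xor(sim$true_assignments == 1L, !flip), "a", "b")
  names(attr_val) <- names(sim$true_assignments)
  cc <- cohort_composition(posterior_modes(fs$fit), attr_val)
  for (g in unique(cc$group)) {
    sub <- cc[cc$group == g, ]
    n_g <- sum(sub$n)
    tol <- 3 * sqrt(0.9 * 0.1 / n_g)
    expect_lt(abs(max(sub$fraction) - 0.9), tol + 1e-9)
  }
})
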