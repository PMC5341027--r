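test_that("stick-breaking weights follow the telescoping construction", {
  expect_equal(stick_breaking_weights(1), 1)
  expect_equal(stick_breaking_weights(c(0.5, 0.5, 1)), c(0.5, 0.25, 0.25))
  set.seed(1)
  for (i in 1:20) {
    K <- sample(2:10, 1L)
    V <- c(runif(K - 1L), 1)
    beta <- stick_breaking_weights(V)
    expect_equal(sum(beta), 1, tolerance = 1e-12)
    expect_true(all(beta >= 0))
  }
  expect_error(stick_breaking_weights(c(0.5, 0.9)), "last")
  expect_error(stick_breaking_weights(c(-0.1, 1)), "\\[0, 1\\]")
})

test_that("membership full conditional normalises the weighted likelihood", {
  # no observations -> prior weights
  expect_equal(assignment_probabilities(c(0, 0), c(0.3, 0.7),
                                        rbind(c(0.5, 0.5), c(0.2, 0.8))),
               c(0.3, 0.7))
  # single group is certain
  expect_equal(assignment_probabilities(c(2, 1), 1, rbind(c(0.4, 0.6))), 1)
  # direct normalisation: 0.5*0.9 vs 0.5*0.1
  expect_equal(assignment_probabilities(c(1, 0), c(0.5, 0.5),
                                        rbind(c(0.9, 0.1), c(0.1, 0.9))),
               c(0.9, 0.1))
  # log-space evaluation survives large counts that underflow direct products
  p <- assignment_probabilities(c(500, 500), c(0.5, 0.5),
                                rbind(c(0.6, 0.4), c(0.4, 0.6)))
  expect_equal(sum(p), 1)
  expect_true(all(is.finite(p)))
})

test_that("membership draws match their conditional probabilities", {
  counts1 <- count_matrix(matrix(c(2L, 1L), 1, 2))
  psi <- rbind(c(0.9, 0.1), c(0.1, 0.9))
  # orthogonal supports pin each individual to its own group
  w_orth <- count_matrix(rbind(c(3L, 0L), c(0L, 4L)))
  psi_orth <- rbind(c(1, 0), c(0, 1))
  set.seed(2)
  z <- sample_assignments(w_orth, c(0.5, 0.5), psi_orth)
  expect_equal(z, c(1L, 2L))
  # K = 1 collapses to group 1
  expect_equal(sample_assignments(counts1, 1, rbind(c(0.5, 0.5))), 1L)
  # frequency check: replicate one individual many times; draws are
  # conditionally independent across rows
  n_rep <- 4000L
  w_rep <- count_matrix(matrix(rep(c(2L, 1L), each = n_rep), n_rep, 2))
  p <- assignment_probabilities(c(2, 1), c(0.5, 0.5), psi)
  set.seed(3)
  z <- sample_assignments(w_rep, c(0.5, 0.5), psi)
  freq <- mean(z == 1L)
  se <- sqrt(p[1] * (1 - p[1]) / n_rep)
  expect_lt(abs(freq - p[1]), 3 * se)
})

test_that("stick updates follow the conjugate Beta posterior", {
  hyper <- ibc_hyper(K = 2L, alpha = 0.1)
  # occupancies n = (2, 1): V_1 ~ Beta(1 + 2, 0.1 + 1), mean 3/4.1
  set.seed(4)
  n_rep <- 4000L
  v1 <- replicate(n_rep, sample_sticks(c(1L, 1L, 2L), hyper)$V[1L])
  target <- 3 / 4.1
  sd_beta <- sqrt(3 * 1.1 / (4.1^2 * 5.1))
  expect_lt(abs(mean(v1) - target), 4 * sd_beta / sqrt(n_rep))
  # K = 1 is degenerate
  s <- sample_sticks(rep(1L, 5L), ibc_hyper(K = 1L))
  expect_equal(s$V, 1)
  expect_equal(s$beta, 1)
  # last stick always 1, beta a simplex
  s <- sample_sticks(rep(1L, 3L), ibc_hyper(K = 25L))
  expect_equal(s$V[25L], 1)
  expect_equal(sum(s$beta), 1, tolerance = 1e-12)
})

test_that("profile updates follow the conjugate Dirichlet posterior", {
  counts <- count_matrix(rbind(c(3L, 1L)))
  hyper <- ibc_hyper(K = 2L, epsilon = 0.1)
  set.seed(5)
  n_rep <- 4000L
  draws <- replicate(n_rep, sample_profiles(counts, 1L, hyper))
  # group 1 sees counts (3, 1): Dirichlet(3.1, 1.1), mean (3.1, 1.1)/4.2
  m1 <- rowMeans(draws[1L, , ])
  target <- c(3.1, 1.1) / 4.2
  se <- sqrt(target * (1 - target) / 5.2) / sqrt(n_rep)
  expect_true(all(abs(m1 - target) < 4 * se))
  # group 2 is empty: prior Dirichlet(0.1, 0.1), mean uniform
  m2 <- rowMeans(draws[2L, , ])
  se2 <- sqrt(0.5 * 0.5 / 1.2) / sqrt(n_rep)
  expect_true(all(abs(m2 - 0.5) < 4 * se2))
  # L = 1 forces every row to 1
  p <- sample_profiles(count_matrix(matrix(2L, 2, 1)), c(1L, 1L), hyper)
  expect_equal(unname(p), matrix(1, 2, 1))
})

test_that("log-likelihood matches direct evaluation on small instances", {
  # single Bernoulli-like term
  expect_equal(log_likelihood(count_matrix(matrix(c(1L, 0L), 1, 2)),
                              1, rbind(c(0.25, 0.75))),
               log(0.25))
  # L = 1: probability part vanishes, coefficients are 0
  expect_equal(log_likelihood(count_matrix(matrix(c(4L, 2L), 2, 1)),
                              1, rbind(1)), 0)
  # brute-force mixture sum without log-space tricks
  set.seed(6)
  for (i in 1:10) {
    J <- sample(1:4, 1L); L <- sample(2:3, 1L); K <- sample(1:3, 1L)
    w <- matrix(rpois(J * L, 2), J, L)
    w[rowSums(w) == 0, 1L] <- 1L
    counts <- count_matrix(w)
    beta <- as.numeric(rmultinom(1, 100, rep(1, K))) / 100
    if (any(beta == 0)) beta <- (beta + 0.01) / sum(beta + 0.01)
    psi <- matrix(rgamma(K * L, 1), K, L); psi <- psi / rowSums(psi)
    brute <- sum(sapply(seq_len(J), function(j) {
      lik <- sum(sapply(seq_len(K), function(k) {
        beta[k] * dmultinom(w[j, ], prob = psi[k, ])
      }))
      log(lik)
    }))
    expect_equal(log_likelihood(counts, beta, psi), brute, tolerance = 1e-10)
  }
})

test_that("count-matrix validation rejects malformed input", {
  expect_error(count_matrix(rbind(c(1, -1))), "row 1, column 2")
  expect_error(count_matrix(rbind(c(1.5, 0))), "integers")
  expect_error(count_matrix(rbind(c(0, 0), c(1, 0))), "ind001")
  expect_error(count_matrix(rbind(1:2, 3:4), row_labels = c("a", "a")),
               "duplicate")
  expect_error(count_matrix(rbind(1:2), col_labels = c("x", "x")),
               "duplicate")
  w <- count_matrix(rbind(c(1L, 0L), c(0L, 2L)))
  expect_equal(unname(row_totals(w)), c(1, 2))
})
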