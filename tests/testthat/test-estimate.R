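# Empirical moments, binomial-thinning correction, gradient matching and
# bootstrap variability.

test_that("empirical moments use unbiased estimators", {
  s <- snapshot_series(c(0, 1), list(matrix(c(0L, 2L), 2, 1),
                                     matrix(c(1L, 1L), 2, 1)), "A")
  m <- empirical_moments(s, max_order = 2L)
  expect_equal(unname(m$values["M1", 1]), 1)      # mean of {0, 2}
  expect_equal(unname(m$values["M1.1", 1]), 2)    # ((0-1)^2 + (2-1)^2) / (2-1)
  expect_equal(unname(m$values["M1.1", 2]), 0)

  # identical cells: all central moments of order >= 2 vanish
  s2 <- snapshot_series(0, list(matrix(5L, 6, 2)), c("A", "B"))
  m2 <- empirical_moments(s2, max_order = 3L)
  expect_true(all(m2$values[moment_order(rownames(m2$values)) >= 2, ] == 0))

  # a sample symmetric about its mean has zero third central moment
  s3 <- snapshot_series(0, list(matrix(c(1L, 2L, 2L, 3L), 4, 1)), "A")
  m3 <- empirical_moments(s3, max_order = 3L)
  expect_equal(unname(m3$values["M1.1.1", 1]), 0)

  expect_error(empirical_moments(
    snapshot_series(0, list(matrix(1L, 2, 1)), "A"), max_order = 3L),
    "at least 4")
})

test_that("noise correction inverts the order-1/2 thinning identities", {
  mk_series <- function(vals) structure(
    list(times = 0, values = matrix(vals, ncol = 1,
                                    dimnames = list(names(vals), NULL)),
         n_cells = 100L, noise_p = 0.5, species = "A"),
    class = "moment_series")
  m <- mk_series(c(M1 = 2, M1.1 = 3))
  out <- correct_binomial_noise(m, 0.5)
  expect_equal(unname(out$values["M1", 1]), 4)             # E[X] = E[X_obs]/p
  expect_equal(unname(out$values["M1.1", 1]), 8)           # (3 - 0.25*4)/0.25
  ident <- correct_binomial_noise(mk_series(c(M1 = 2, M1.1 = 3)), 1)
  expect_equal(ident$values[, 1], c(M1 = 2, M1.1 = 3))
  expect_error(correct_binomial_noise(m, 0), "0, 1")
  expect_warning(correct_binomial_noise(mk_series(c(M1 = 10, M1.1 = 0.1)), 0.1),
                 "clipped")
})

test_that("factorial-moment inversion is exact for binomial thinning up to order 3", {
  # forward map computed independently by exact enumeration of Bi(x, p)
  pop_central <- function(xs1, xs2) {
    mu <- c(mean(xs1), mean(xs2))
    d1 <- xs1 - mu[1]; d2 <- xs2 - mu[2]
    c(M1 = mu[1], M2 = mu[2],
      M1.1 = mean(d1^2), M1.2 = mean(d1 * d2), M2.2 = mean(d2^2),
      M1.1.1 = mean(d1^3), M1.1.2 = mean(d1^2 * d2),
      M1.2.2 = mean(d1 * d2^2), M2.2.2 = mean(d2^3))
  }
  thinned_raw <- function(x, r, p) {   # E[B^r], B ~ Bi(x, p), exact
    k <- 0:x
    sum(dbinom(k, x, p) * k^r)
  }
  xs1 <- c(0, 3, 7, 12, 5); xs2 <- c(2, 2, 9, 1, 6)
  p <- 0.3
  # population raw moments of the thinned pair (independent thinning)
  raws <- function(a, b) mean(vapply(seq_along(xs1), function(i)
    thinned_raw(xs1[i], a, p) * thinned_raw(xs2[i], b, p), numeric(1)))
  mu <- c(raws(1, 0), raws(0, 1))
  raw_to_central <- function() {
    m2 <- c(raws(2, 0), raws(1, 1), raws(0, 2))
    m3 <- c(raws(3, 0), raws(2, 1), raws(1, 2), raws(0, 3))
    C <- c(m2[1] - mu[1]^2, m2[2] - mu[1] * mu[2], m2[3] - mu[2]^2)
    c(M1 = mu[1], M2 = mu[2], M1.1 = C[1], M1.2 = C[2], M2.2 = C[3],
      M1.1.1 = m3[1] - 3 * mu[1] * C[1] - mu[1]^3,
      M1.1.2 = m3[2] - 2 * mu[1] * C[2] - mu[2] * C[1] - mu[1]^2 * mu[2],
      M1.2.2 = m3[3] - 2 * mu[2] * C[2] - mu[1] * C[3] - mu[1] * mu[2]^2,
      M2.2.2 = m3[4] - 3 * mu[2] * C[3] - mu[2]^3)
  }
  v_obs <- raw_to_central()
  keys <- moment_basis(2, 3)
  got <- reactionet:::correct_moment_vector(v_obs[keys], p)
  expect_equal(got[keys], pop_central(xs1, xs2)[keys], tolerance = 1e-10)
})

test_that("gradient estimators are exact on constant and linear series", {
  t <- c(0, 0.7, 1.5, 2.2, 4)
  mk <- function(y) structure(
    list(times = t, values = matrix(y, 1, length(t),
                                    dimnames = list("M1", NULL)),
         n_cells = rep(10L, length(t)), noise_p = NULL),
    class = "moment_series")
  for (method in c("spline", "fds")) {
    g0 <- estimate_gradients(mk(rep(3, 5)), method, targets = "M1")
    expect_equal(unname(g0$values[1, ]), rep(0, 5))
    glin <- estimate_gradients(mk(2 - 1.5 * t), method, targets = "M1")
    expect_equal(unname(glin$values[1, ]), rep(-1.5, 5), tolerance = 1e-10)
  }
  expect_error(estimate_gradients(mk(rep(1, 5)), "smooth", targets = "M1"),
               "trajectories")
})

test_that("spline gradients beat finite differences on exponential decay", {
  t <- seq(0, 4, length.out = 13)
  m <- structure(
    list(times = t, values = matrix(exp(-t), 1, 13,
                                    dimnames = list("M1", NULL)),
         n_cells = rep(10L, 13), noise_p = NULL),
    class = "moment_series")
  gs <- estimate_gradients(m, "spline", targets = "M1")$values[1, ]
  gf <- estimate_gradients(m, "fds", targets = "M1")$values[1, ]
  interior <- 3:11   # nodes adjacent to the boundary keep some endpoint bias
  rel_s <- abs((gs[interior] + exp(-t[interior])) / exp(-t[interior]))
  expect_lt(max(rel_s), 0.02)
  both <- 2:12
  expect_gte(sum(abs(gf[both] + exp(-t[both]))),
             sum(abs(gs[both] + exp(-t[both]))))
})

test_that("smooth gradients recover ensemble dynamics from dense trajectories", {
  death <- reaction_network("A", list(reaction(1L, integer(0), 1)))
  t_grid <- c(0.5, 1, 1.5, 2)
  s <- ssa_simulate(death, 200L, t_grid, 3000, seed = 6,
                    keep_trajectories = TRUE, dense_n = 81L)
  m <- empirical_moments(s, max_order = 2L)
  g <- estimate_gradients(m, "smooth",
                          trajectories = attr(s, "trajectories"),
                          targets = "M1")
  truth <- -200 * exp(-t_grid)
  expect_lt(max(abs(g$values[1, ] - truth) / abs(truth)), 0.1)
})

test_that("bootstrap SDs are reproducible, vanish on degenerate data and scale like 1/sqrt(C)", {
  death <- reaction_network("A", list(reaction(1L, integer(0), 1)))
  eqs <- derive_moment_equations(death, 2L)

  const <- snapshot_series(c(0, 1, 2), rep(list(matrix(9L, 10, 1)), 3), "A")
  bdeg <- bootstrap_variability(const, eqs, B = 50L, seed = 1)
  expect_true(all(bdeg$moment_sd == 0))
  expect_true(all(bdeg$gradient_sd == 0))
  expect_true(all(bdeg$design_sd == 0))

  s1 <- ssa_simulate(death, 100L, c(0.2, 0.6, 1.2), 400, seed = 2)
  b1 <- bootstrap_variability(s1, eqs, B = 300L, seed = 3)
  b1b <- bootstrap_variability(s1, eqs, B = 300L, seed = 3)
  expect_identical(b1, b1b)

  s4 <- ssa_simulate(death, 100L, c(0.2, 0.6, 1.2), 1600, seed = 2)
  b4 <- bootstrap_variability(s4, eqs, B = 300L, seed = 3)
  ratio <- b4$moment_sd["M1", ] / b1$moment_sd["M1", ]
  expect_true(all(abs(ratio - 0.5) < 0.1))
  expect_error(bootstrap_variability(s1, eqs, B = 1L), "B >= 2")
})
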