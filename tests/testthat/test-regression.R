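# Regression-system assembly, the FGLS step, the ADMM adaptive relaxed
# lasso and model selection.

# Assemble a system from analytic inputs: random moment values per time
# point, gradients set exactly to sum_l k_l F_l (a noiseless consistent
# system), unit SDs.
noiseless_system <- function(lib, k_true, T_ = 9L, seed = 1, orders = "2") {
  eqs <- derive_moment_equations(lib, max_order = if (orders == "2") 2L else 1L)
  ev <- design_evaluator(eqs)
  n_sp <- length(lib$network$species)
  keys <- moment_basis(n_sp, 3L)
  vals <- withr::with_seed(seed,
    matrix(runif(length(keys) * T_, 1, 50), length(keys), T_,
           dimnames = list(keys, NULL)))
  m <- structure(list(times = seq_len(T_), values = vals,
                      n_cells = rep(100L, T_), noise_p = NULL),
                 class = "moment_series")
  grads <- vapply(seq_len(T_), function(j)
    as.numeric(eval_design(ev, vals[, j]) %*% k_true),
    numeric(length(eqs$targets)))
  rownames(grads) <- eqs$targets
  g <- structure(list(times = seq_len(T_), values = grads, method = "spline"),
                 class = "gradient_series")
  sd <- list(gradient_sd = matrix(1, length(eqs$targets), T_,
                                  dimnames = list(eqs$targets, NULL)),
             design_sd = array(1, c(length(eqs$targets), eqs$L, T_)))
  assemble_system(eqs, m, g, sd, orders = orders)
}

test_that("system assembly follows the block layout and row counts", {
  # 14 species, orders <= 2, T = 13: (14 means + 105 second moments) x 13
  net14 <- fixture_network("random_sparse", n_species = 14L,
                           n_reactions = 5L, seed = 1L)
  lib14 <- structure(list(network = reaction_network(net14$species,
    lapply(net14$reactions, function(r) reaction(r$reactants, r$products))),
    known = logical(5)), class = "candidate_library")
  sys14 <- noiseless_system(lib14, rep(0.1, 5), T_ = 13L)
  expect_length(sys14$b, 1547L)
  expect_equal(nrow(sys14$A), 1547L)
  # block-major ordering: first 13 rows all belong to the first mean target
  expect_equal(unique(sys14$row_target[1:13]), "M1")
  expect_equal(sys14$row_time[1:13], 1:13)

  lib4 <- enz_library()
  expect_length(noiseless_system(lib4, rep(0, 30), T_ = 7L, orders = "1")$b, 28L)
  expect_length(noiseless_system(lib4, rep(0, 30), T_ = 7L, orders = "2")$b, 98L)
})

test_that("FG step recovers a noiseless consistent nonnegative system", {
  lib <- enz_library()
  k_true <- numeric(30)
  k_true[c(19, 13, 14)] <- c(0.002, 0.1, 0.3)
  sys <- noiseless_system(lib, k_true)
  fg <- step1_fg(sys)
  expect_equal(fg$k_fg, k_true, tolerance = 1e-6)
  expect_true(all(which(k_true > 0) %in% fg$support))
  # all-equal SDs: FG estimate equals the plain NNLS estimate
  sys2 <- sys
  sys2$sd_b <- rep(2.5, length(sys$b))
  sys2$sd_A <- matrix(2.5, nrow(sys$A), ncol(sys$A))
  fg2 <- step1_fg(sys2)
  plain <- pracma::lsqnonneg(sys$A, sys$b)$x
  expect_equal(fg2$k_fg, plain, tolerance = 1e-6)
})

test_that("zero residual variances are floored with a warning", {
  A <- withr::with_seed(1, matrix(abs(rnorm(40)), 20, 2))
  b <- as.numeric(A %*% c(1, 2))
  sys <- synth_system(A, b, sd_b = c(0, rep(1, 19)),
                      sd_A = matrix(0, 20, 2))
  expect_warning(fg <- step1_fg(sys), "floored")
  expect_true(all(fg$sigma_eps > 0))
})

test_that("whitened residuals have unit scale under the true model", {
  withr::with_seed(4, {
    A <- matrix(abs(rnorm(4000)), 200, 20)
    k <- c(runif(3, 0.5, 2), numeric(17))
    sigma <- runif(200, 0.5, 5)
    b <- as.numeric(A %*% k) + rnorm(200, sd = sigma)
  })
  sys <- synth_system(A, b, sd_b = sigma, sd_A = matrix(0, 200, 20))
  fg <- step1_fg(sys)
  res <- fg$bS - as.numeric(fg$AS %*% k)
  expect_lt(abs(stats::var(res) - 1), 0.35)
})

test_that("the ADMM solver reproduces one-dimensional closed forms", {
  admm <- reactionet:::admm_wlasso
  # single orthonormal column, a'b = 3, ktilde = 1: minimizing
  # (3 - k)^2 + 2k over k >= 0 gives k = 2; the relaxed refit gives 3
  A1 <- matrix(c(1, numeric(9)), 10, 1)
  b1 <- c(3, numeric(9))
  f <- admm(A1, b1, w = 1, lambda = 2)
  expect_equal(f$k, 2, tolerance = 1e-6)
  fg <- structure(list(support = 1L, weights = 1, bS = b1, AS = A1,
                       prior = integer(0)), class = "fg_result")
  path <- step2_adaptive_relaxed_lasso(fg, lambda = 2, seed = 1)
  expect_equal(path$coef[1, 1], 3, tolerance = 1e-8)
  # lambda = 0: the ADMM solution equals NNLS
  A <- withr::with_seed(2, matrix(abs(rnorm(200)), 40, 5))
  b <- as.numeric(A %*% c(1, 0, 2, 0, 0.3)) + withr::with_seed(3, rnorm(40, sd = 0.2))
  f0 <- admm(A, b, w = rep(1, 5), lambda = 0)
  expect_equal(f0$k, pracma::lsqnonneg(A, b)$x, tolerance = 1e-5)
})

test_that("the analytic lambda_max zeroes every non-prior coefficient", {
  withr::with_seed(5, {
    A <- matrix(abs(rnorm(300)), 50, 6)
    b <- as.numeric(A %*% c(2, 0, 1, 0, 0, 0.5)) + rnorm(50, sd = 0.1)
  })
  fg <- structure(list(support = 1:6,
                       weights = abs(as.numeric(pracma::pinv(A) %*% b)) + 1e-3,
                       bS = b, AS = A, prior = integer(0)),
                  class = "fg_result")
  path <- step2_adaptive_relaxed_lasso(fg, nlambda = 20L, seed = 1)
  expect_length(path$active[[1]], 0L)
  expect_true(all(path$coef[, 1] == 0))
  # KKT bound: any lambda above 2 max_i ktilde_i (A'b)_i also zeroes all
  lam_big <- 2 * max(fg$weights * pmax(crossprod(A, b), 0)) * 1.01
  f <- reactionet:::admm_wlasso(A, b, 1 / fg$weights, lam_big)
  expect_true(all(f$k == 0))
  # the active set grows (weakly) as lambda decreases
  sizes <- lengths(path$active)
  expect_true(all(diff(sizes) >= 0))
})

test_that("model selection handles single-lambda paths and prefers sparse truth", {
  withr::with_seed(6, {
    A <- matrix(abs(rnorm(240)), 40, 6)
    k_true <- c(1.5, 0, 0.8, 0, 0, 0)
    b <- as.numeric(A %*% k_true)
  })
  fg <- structure(list(support = 1:6, weights = rep(1, 6), bS = b, AS = A,
                       prior = integer(0)), class = "fg_result")
  p1 <- step2_adaptive_relaxed_lasso(fg, lambda = 1e-4, seed = 1)
  s1 <- select_model(p1)
  expect_equal(s1$lambda_star, 1e-4)
  full <- step2_adaptive_relaxed_lasso(fg, nlambda = 30L, seed = 1)
  sel <- select_model(full)
  expect_setequal(sel$selected, c(1L, 3L))
  expect_equal(unname(sel$k_hat[order(sel$selected)]), c(1.5, 0.8),
               tolerance = 1e-4)
  # duplicating a spurious collinear column never lowers the selected BIC
  A2 <- cbind(A, A[, 2])
  fg2 <- structure(list(support = 1:7, weights = rep(1, 7), bS = b, AS = A2,
                        prior = integer(0)), class = "fg_result")
  sel2 <- select_model(step2_adaptive_relaxed_lasso(fg2, nlambda = 30L, seed = 1))
  expect_gte(sel2$bic_star, sel$bic_star - 1e-8)
  expect_error(select_model(structure(list(lambda = numeric(0)),
                                      class = "path_result")), "empty")
})

test_that("prior-knowledge reactions survive every step", {
  withr::with_seed(7, {
    A <- matrix(abs(rnorm(300)), 50, 6)
    b <- as.numeric(A %*% c(2, 0, 1, 0, 0, 0)) + rnorm(50, sd = 0.05)
  })
  # declare a spurious reaction (column 5) as prior knowledge
  sys <- synth_system(A, b, sd_b = rep(1, 50), sd_A = matrix(0, 50, 6))
  res <- reactionet_lasso(sys, prior = 5L, seed = 1)
  expect_true(5L %in% res$fg$support)
  expect_true(5L %in% res$selection$selected)
  expect_true(all(c(1L, 3L) %in% res$selection$selected))
})

test_that("replicate concatenation stacks rows and preserves the FG argmin", {
  lib <- enz_library()
  k_true <- numeric(30); k_true[c(19, 13, 14)] <- c(0.002, 0.1, 0.3)
  sys <- noiseless_system(lib, k_true)
  expect_identical(concat_replicates(list(sys)), sys)
  dbl <- concat_replicates(list(sys, sys))
  expect_length(dbl$b, 2 * length(sys$b))
  fg1 <- step1_fg(sys); fg2 <- step1_fg(dbl)
  expect_equal(fg1$k_fg, fg2$k_fg, tolerance = 1e-6)
  other <- synth_system(matrix(1, 4, 2), rep(1, 4))
  expect_error(concat_replicates(list(sys, other)), "mismatched")
})

test_that("assembly validates missing inputs by name", {
  lib <- enz_library()
  eqs <- derive_moment_equations(lib, 2L)
  keys <- moment_basis(4, 3)
  vals <- matrix(1, length(keys), 3, dimnames = list(keys, NULL))
  m <- structure(list(times = 1:3, values = vals, n_cells = rep(10L, 3),
                      noise_p = NULL), class = "moment_series")
  g_bad <- structure(list(times = 1:3,
                          values = matrix(0, 1, 3, dimnames = list("M1", NULL)),
                          method = "spline"), class = "gradient_series")
  sd <- list(gradient_sd = vals[eqs$targets, ] * 0,
             design_sd = array(0, c(14, 30, 3)))
  expect_error(assemble_system(eqs, m, g_bad, sd), "missing target M2")
  m_bad <- m
  m_bad$values <- vals[setdiff(keys, "M1.2"), ]
  g_ok <- structure(list(times = 1:3,
                         values = matrix(0, 14, 3,
                                         dimnames = list(eqs$targets, NULL)),
                         method = "spline"), class = "gradient_series")
  expect_error(assemble_system(eqs, m_bad, g_ok, sd), "M1.2")
})
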