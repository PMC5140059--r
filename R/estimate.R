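# Empirical central moments of snapshot ensembles, binomial-thinning noise
# correction, gradient matching, and bootstrap variability of the whole
# estimator pipeline.

# Moments of one counts matrix (cells x species) as a named vector over the
# canonical moment basis. Order 1: sample means; order 2: unbiased sample
# (co)variances (divisor C-1); order 3: unbiased h-statistic
# C^2/((C-1)(C-2)) * mean of deviation products.
moment_vector <- function(m, max_order = 3L) {
  C <- nrow(m); n <- ncol(m)
  if (C < 2L) stop("moment estimation needs at least 2 cells")
  if (max_order >= 3L && C < 4L)
    stop("third-order moment estimation needs at least 4 cells")
  keys <- moment_basis(n, max_order)
  v <- setNames(numeric(length(keys)), keys)
  mu <- colMeans(m)
  v[seq_len(n)] <- mu
  if (max_order >= 2L) {
    D <- sweep(m, 2L, mu)
    S2 <- crossprod(D) / (C - 1)
    for (i in seq_len(n)) v[moment_key(c(i, i))] <- S2[i, i]
    if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n)
      v[moment_key(c(i, j))] <- S2[i, j]
    if (max_order >= 3L) {
      f3 <- C^2 / ((C - 1) * (C - 2))
      for (i in seq_len(n)) for (j in i:n) for (k in j:n)
        v[moment_key(c(i, j, k))] <- f3 * mean(D[, i] * D[, j] * D[, k])
    }
  }
  v
}

#' Empirical central moments of a snapshot series
#'
#' Per time point: sample means (order 1), unbiased sample (co)variances
#' (order 2, divisor C-1), and unbiased third central moments (order 3,
#' h-statistic with factor C^2/((C-1)(C-2))).
#'
#' @param s a `snapshot_series`.
#' @param max_order 2 or 3.
#' @return an object of class `moment_series`: `times`, `values` (moment
#'   keys x time points), `n_cells`, and the series' `noise_p`.
#' @export
empirical_moments <- function(s, max_order = 3L) {
  stopifnot(inherits(s, "snapshot_series"), max_order %in% 2:3)
  vals <- vapply(s$counts, moment_vector,
                 moment_vector(s$counts[[1]], max_order), max_order = max_order)
  structure(list(times = s$times, values = vals,
                 n_cells = vapply(s$counts, nrow, 0L),
                 noise_p = s$noise_p, species = s$species),
            class = "moment_series")
}

# Correct one named moment vector for binomial thinning with known capture
# efficiency p, via falling-factorial-moment inversion:
# E[(X_obs)_(r)] = p^|r| E[(X)_(r)] coordinate-wise, exact for the binomial
# model. Reproduces E[X] = E[X_obs]/p, Var[X] = (Var[X_obs]-p(1-p)E[X])/p^2
# and cov/p^2 at orders 1-2.
correct_moment_vector <- function(v, p) {
  keys <- names(v)
  ord <- moment_order(keys)
  n <- max(unlist(lapply(keys, parse_moment_key)))
  mu_obs <- v[paste0("M", seq_len(n))]

  # observed central -> observed raw moments
  raw_obs <- v
  for (i in which(ord == 2L)) {
    ij <- parse_moment_key(keys[i])
    raw_obs[i] <- v[i] + mu_obs[ij[1]] * mu_obs[ij[2]]
  }
  for (i in which(ord == 3L)) {
    ijk <- parse_moment_key(keys[i])
    a <- ijk[1]; b <- ijk[2]; cc <- ijk[3]
    raw_obs[i] <- v[i] +
      mu_obs[a] * v[moment_key(c(b, cc))] +
      mu_obs[b] * v[moment_key(c(a, cc))] +
      mu_obs[cc] * v[moment_key(c(a, b))] +
      mu_obs[a] * mu_obs[b] * mu_obs[cc]
  }

  # raw -> factorial (per coordinate, exponents <= 3), scale by p^-order,
  # factorial -> raw
  fact_of_raw <- function(raw, key) {
    idx <- parse_moment_key(key)
    tab <- table(idx)
    if (length(tab) == length(idx)) return(raw[key])      # all exponents 1
    if (length(idx) == 2L) return(raw[key] - raw[moment_key(idx[1])])  # (i,i)
    if (length(tab) == 1L)                                # (i,i,i)
      return(raw[key] - 3 * raw[moment_key(idx[1:2])] + 2 * raw[moment_key(idx[1])])
    # (i,i,j): subtract E[X_i X_j]
    rep2 <- as.integer(names(tab)[tab == 2L])
    oth <- as.integer(names(tab)[tab == 1L])
    raw[key] - raw[moment_key(c(rep2, oth))]
  }
  f_true <- setNames(numeric(length(keys)), keys)
  for (k in keys) f_true[k] <- fact_of_raw(raw_obs, k) / p^moment_order(k)

  raw_true <- f_true
  for (k in keys[ord == 2L]) {
    idx <- parse_moment_key(k)
    if (idx[1] == idx[2]) raw_true[k] <- f_true[k] + raw_true[moment_key(idx[1])]
  }
  for (k in keys[ord == 3L]) {
    idx <- parse_moment_key(k)
    tab <- table(idx)
    if (length(tab) == 3L) next
    if (length(tab) == 1L)
      raw_true[k] <- f_true[k] + 3 * raw_true[moment_key(idx[1:2])] -
        2 * raw_true[moment_key(idx[1])]
    else {
      rep2 <- as.integer(names(tab)[tab == 2L])
      oth <- as.integer(names(tab)[tab == 1L])
      raw_true[k] <- f_true[k] + raw_true[moment_key(c(rep2, oth))]
    }
  }

  # raw -> central about the corrected means
  mu <- raw_true[paste0("M", seq_len(n))]
  out <- raw_true
  for (k in keys[ord == 2L]) {
    ij <- parse_moment_key(k)
    out[k] <- raw_true[k] - mu[ij[1]] * mu[ij[2]]
  }
  for (k in keys[ord == 3L]) {
    ijk <- parse_moment_key(k)
    a <- ijk[1]; b <- ijk[2]; cc <- ijk[3]
    out[k] <- raw_true[k] -
      mu[a] * out[moment_key(c(b, cc))] -
      mu[b] * out[moment_key(c(a, cc))] -
      mu[cc] * out[moment_key(c(a, b))] -
      mu[a] * mu[b] * mu[cc]
  }
  out
}

clip_negative_variances <- function(v, warn = TRUE) {
  ord <- moment_order(names(v))
  for (i in which(ord == 2L)) {
    ij <- parse_moment_key(names(v)[i])
    if (ij[1] == ij[2] && v[i] < 0) {
      if (warn) warning("noise-corrected variance ", names(v)[i],
                        " was negative; clipped to 0", call. = FALSE)
      v[i] <- 0
    }
  }
  v
}

#' Correct empirical moments for binomial capture-efficiency noise
#'
#' Inverts the binomial thinning model X_obs ~ Bi(X, p) on moment estimates
#' of orders 1-3 using the falling-factorial-moment identity
#' E[(X_obs)_(r)] = p^r E[(X)_(r)] coordinate-wise (exact for this model).
#' At orders 1-2 this reduces to E[X] = E[X_obs]/p,
#' Var[X] = (Var[X_obs] - p(1-p)E[X]) / p^2 and cov[X1,X2] = cov_obs / p^2.
#' Corrected variances that come out negative (sampling noise at small p)
#' are clipped to zero with a warning.
#'
#' @param m a `moment_series` computed from noisy data.
#' @param p known capture efficiency in (0, 1].
#' @return a corrected `moment_series` with `noise_p = NULL`.
#' @export
correct_binomial_noise <- function(m, p) {
  stopifnot(inherits(m, "moment_series"))
  if (!(p > 0 && p <= 1)) stop("capture efficiency p must be in (0, 1]")
  vals <- m$values
  for (j in seq_len(ncol(vals)))
    vals[, j] <- clip_negative_variances(correct_moment_vector(vals[, j], p))
  structure(list(times = m$times, values = vals, n_cells = m$n_cells,
                 noise_p = NULL, species = m$species),
            class = "moment_series")
}

## --- gradient matching -----------------------------------------------------

# Derivative of one series by nonuniform finite differences: three-point
# central formulas (exact for quadratics) at interior points, two-point
# one-sided at the ends.
fds_derivative <- function(t, y) {
  T_ <- length(t)
  g <- numeric(T_)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[T_] <- (y[T_] - y[T_ - 1]) / (t[T_] - t[T_ - 1])
  if (T_ > 2L) for (j in 2:(T_ - 1L)) {
    h1 <- t[j] - t[j - 1]; h2 <- t[j + 1] - t[j]
    g[j] <- -h2 / (h1 * (h1 + h2)) * y[j - 1] +
      (h2 - h1) / (h1 * h2) * y[j] +
      h1 / (h2 * (h1 + h2)) * y[j + 1]
  }
  g
}

moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  half <- (window - 1L) %/% 2L
  n <- length(y)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

#' Estimate moment time-derivatives by gradient matching
#'
#' Methods: `"spline"` differentiates the natural cubic interpolating spline
#' through the moment estimates; `"fds"` uses nonuniform-grid finite
#' differences (central interior, one-sided ends); `"smooth"` applies
#' sliding-window finite differences to densely sampled ensemble moments
#' (an oracle available in simulation only, requiring the dense-grid
#' trajectory snapshots).
#'
#' @param m a `moment_series` (noise-corrected where applicable).
#' @param method `"spline"`, `"fds"` or `"smooth"`.
#' @param trajectories dense-grid `snapshot_series` (from
#'   `ssa_simulate(..., keep_trajectories = TRUE)`); required for `"smooth"`.
#' @param targets moment keys to differentiate; defaults to all keys of
#'   order <= 2 present in `m`.
#' @param window moving-average window (grid points) for `"smooth"`.
#' @return an object of class `gradient_series`: `times`, `values`
#'   (targets x time points), `method`.
#' @export
estimate_gradients <- function(m, method = c("spline", "fds", "smooth"),
                               trajectories = NULL, targets = NULL,
                               window = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(m, "moment_series"))
  if (length(m$times) < 3L) stop("gradient estimation needs at least 3 time points")
  if (is.null(targets))
    targets <- rownames(m$values)[moment_order(rownames(m$values)) <= 2L]
  vals <- matrix(0, length(targets), length(m$times),
                 dimnames = list(targets, NULL))
  if (method == "smooth") {
    if (is.null(trajectories))
      stop("the smooth gradient method requires dense trajectories")
    dm <- empirical_moments(trajectories, max_order = 2L)
    for (k in targets) {
      g <- fds_derivative(dm$times, dm$values[k, ])
      g <- moving_average(g, window)
      vals[k, ] <- approx_(dm$times, g, m$times)
    }
  } else {
    for (k in targets) {
      y <- m$values[k, ]
      if (method == "spline") {
        f <- splinefun(m$times, y, method = "natural")
        vals[k, ] <- f(m$times, deriv = 1L)
      } else {
        vals[k, ] <- fds_derivative(m$times, y)
      }
    }
  }
  structure(list(times = m$times, values = vals, method = method),
            class = "gradient_series")
}

approx_ <- function(x, y, xout) stats::approx(x, y, xout = xout, rule = 2)$y

## --- bootstrap variability of the full estimator pipeline ------------------

# One pass of the estimator pipeline on a list of count matrices: moments ->
# noise correction -> gradients -> design-matrix blocks. Returns the pieces
# the regression system is built from.
estimator_pass <- function(counts, times, ev, max_order, p = NULL,
                           gradient_method = "spline", targets,
                           trajectories = NULL, window = 5L) {
  vals <- vapply(counts, moment_vector,
                 moment_vector(counts[[1]], max_order), max_order = max_order)
  if (!is.null(p) && p < 1) {
    for (j in seq_len(ncol(vals)))
      vals[, j] <- clip_negative_variances(correct_moment_vector(vals[, j], p),
                                           warn = FALSE)
  }
  m <- structure(list(times = times, values = vals,
                      n_cells = vapply(counts, nrow, 0L), noise_p = NULL),
                 class = "moment_series")
  g <- estimate_gradients(m, gradient_method, trajectories = trajectories,
                          targets = targets, window = window)
  design <- vapply(seq_along(times),
                   function(j) eval_design(ev, vals[, j]),
                   matrix(0, length(ev$targets), ev$L))
  list(moments = vals, gradients = g$values, design = design)
}

#' Bootstrap variability of moments, gradients and design entries
#'
#' Per time point, cells are resampled with replacement B times and the full
#' estimator pipeline (moments, noise correction, gradient matching, design
#' evaluation) is re-run on every replicate. The reported standard
#' deviations feed the residual-variance model of the FGLS step.
#'
#' @param s a `snapshot_series` (noisy or clean).
#' @param eqs `moment_equations` for the candidate library.
#' @param B number of bootstrap replicates (>= 2; default 200).
#' @param seed integer seed.
#' @param gradient_method gradient matching method (see
#'   [estimate_gradients()]).
#' @param trajectories dense-grid series for the `"smooth"` method.
#' @param window smoothing window for the `"smooth"` method.
#' @return a list with `moment_sd` (keys x T), `gradient_sd` (targets x T),
#'   `design_sd` (targets x L x T array) and the point-estimate pipeline
#'   outputs `point` (same shapes, no sd).
#' @export
bootstrap_variability <- function(s, eqs, B = 200L, seed = 1L,
                                  gradient_method = "spline",
                                  trajectories = NULL, window = 5L) {
  stopifnot(inherits(s, "snapshot_series"), inherits(eqs, "moment_equations"))
  if (B < 2L) stop("bootstrap needs B >= 2 replicates")
  ev <- design_evaluator(eqs)
  need_ord <- max(c(1L, moment_order(ev$needed)))
  max_order <- max(2L, need_ord)
  targets <- eqs$targets
  p <- s$noise_p
  T_ <- length(s$times)

  point <- estimator_pass(s$counts, s$times, ev, max_order, p,
                          gradient_method, targets, trajectories, window)

  nm <- nrow(point$moments); nt <- length(targets); L <- eqs$L
  mom_acc <- array(0, c(nm, T_, B))
  grad_acc <- array(0, c(nt, T_, B))
  des_acc <- array(0, c(nt, L, T_, B))
  with_seed(derive_seed(seed, "bootstrap"), {
    joint <- identical(gradient_method, "smooth")
    for (b in seq_len(B)) {
      if (joint) {
        C <- nrow(s$counts[[1]])
        idx <- sample.int(C, C, replace = TRUE)
        counts_b <- lapply(s$counts, function(m) m[idx, , drop = FALSE])
        traj_b <- trajectories
        traj_b$counts <- lapply(trajectories$counts,
                                function(m) m[idx, , drop = FALSE])
      } else {
        counts_b <- lapply(s$counts, function(m) {
          m[sample.int(nrow(m), nrow(m), replace = TRUE), , drop = FALSE]
        })
        traj_b <- NULL
      }
      r <- estimator_pass(counts_b, s$times, ev, max_order, p,
                          gradient_method, targets, traj_b, window)
      mom_acc[, , b] <- r$moments
      grad_acc[, , b] <- r$gradients
      des_acc[, , , b] <- r$design
    }
  })
  sd_over <- function(a) apply(a, seq_len(length(dim(a)) - 1L), sd)
  out <- list(moment_sd = sd_over(mom_acc), gradient_sd = sd_over(grad_acc),
              design_sd = sd_over(des_acc), point = point, B = B, seed = seed)
  rownames(out$moment_sd) <- rownames(point$moments)
  rownames(out$gradient_sd) <- targets
  out
}

#' Export a moment or gradient series as a delimited table
#' @param x a `moment_series` or `gradient_series`.
#' @param path output path (tab-separated).
#' @param boot_sd optional matrix of bootstrap SDs aligned with `x$values`.
#' @return `path`, invisibly.
#' @export
write_series_table <- function(x, path, boot_sd = NULL) {
  keys <- rownames(x$values)
  dt <- data.table::data.table(
    moment_index = rep(keys, times = length(x$times)),
    time = rep(x$times, each = length(keys)),
    estimate = as.vector(x$values),
    boot_sd = if (is.null(boot_sd)) NA_real_ else as.vector(boot_sd))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
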