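# The reactionet lasso: gradient-matching regression assembly, the FGLS
# reduction step, the ADMM adaptive relaxed lasso with cross-validation and
# stability selection, and BIC-guided backward model refinement.

#' Assemble the gradient-matching regression system
#'
#' Stacks the moment-gradient estimates into the response vector b and the
#' stoichiometric moment function evaluations into the design matrix A,
#' moment-block-major then time: all rows of the first target moment at
#' t_1..t_T, then the second target, and so on. `orders = "1"` keeps only
#' the mean rows (the deterministic first-order baseline); `orders = "2"`
#' uses means, variances and covariances.
#'
#' @param eqs `moment_equations` for the candidate library.
#' @param m a noise-corrected `moment_series` covering
#'   `required_input_moments(eqs)`.
#' @param g a `gradient_series` covering all targets and time points.
#' @param sd bootstrap output of [bootstrap_variability()] (uses
#'   `gradient_sd` and `design_sd`).
#' @param orders `"2"` (default) or `"1"`.
#' @return an object of class `regression_system` with fields `b`, `A`,
#'   `sd_b`, `sd_A`, `row_target`, `row_time`, `L`.
#' @export
assemble_system <- function(eqs, m, g, sd, orders = c("2", "1")) {
  orders <- match.arg(orders)
  stopifnot(inherits(eqs, "moment_equations"), inherits(m, "moment_series"))
  targets <- eqs$targets
  if (orders == "1") targets <- targets[moment_order(targets) == 1L]
  miss <- setdiff(required_input_moments(eqs), rownames(m$values))
  if (length(miss)) stop("moment series is missing required moment ", miss[1])
  gm <- setdiff(targets, rownames(g$values))
  if (length(gm)) stop("gradient series is missing target ", gm[1])
  T_ <- length(m$times)
  if (length(g$times) != T_ || any(abs(g$times - m$times) > 1e-9))
    stop("moment and gradient series are on different time grids")
  ev <- design_evaluator(eqs)
  L <- eqs$L
  nt <- length(targets)
  b <- numeric(nt * T_); A <- matrix(0, nt * T_, L)
  sd_b <- numeric(nt * T_); sd_A <- matrix(0, nt * T_, L)
  row_target <- character(nt * T_); row_time <- numeric(nt * T_)
  ti_map <- match(targets, eqs$targets)
  design <- vapply(seq_len(T_), function(j) eval_design(ev, m$values[, j]),
                   matrix(0, length(eqs$targets), L))
  for (i in seq_len(nt)) {
    rows <- (i - 1L) * T_ + seq_len(T_)
    b[rows] <- g$values[targets[i], ]
    sd_b[rows] <- sd$gradient_sd[targets[i], ]
    A[rows, ] <- t(design[ti_map[i], , ])
    sd_A[rows, ] <- t(sd$design_sd[ti_map[i], , ])
    row_target[rows] <- targets[i]
    row_time[rows] <- m$times
  }
  structure(list(b = b, A = A, sd_b = sd_b, sd_A = sd_A,
                 row_target = row_target, row_time = row_time,
                 L = L, orders = orders, targets = targets),
            class = "regression_system")
}

#' Concatenate regression systems from replicate experiments
#'
#' Stacks rows of replicate (or condition-specific) systems sharing the same
#' candidate library; all downstream steps operate unchanged on the result.
#'
#' @param systems list of `regression_system` objects over identical
#'   candidate libraries.
#' @return a single `regression_system`.
#' @export
concat_replicates <- function(systems) {
  stopifnot(length(systems) >= 1L)
  if (length(systems) == 1L) return(systems[[1]])
  L <- systems[[1]]$L
  for (s in systems)
    if (s$L != L || !identical(s$orders, systems[[1]]$orders))
      stop("replicate systems use mismatched candidate libraries")
  structure(list(
    b = unlist(lapply(systems, `[[`, "b")),
    A = do.call(rbind, lapply(systems, `[[`, "A")),
    sd_b = unlist(lapply(systems, `[[`, "sd_b")),
    sd_A = do.call(rbind, lapply(systems, `[[`, "sd_A")),
    row_target = unlist(lapply(systems, `[[`, "row_target")),
    row_time = unlist(lapply(systems, `[[`, "row_time")),
    L = L, orders = systems[[1]]$orders, targets = systems[[1]]$targets),
    class = "regression_system")
}

# Nonnegative least squares with an optional strict-positivity floor on
# prior-knowledge columns (substituted out so Lawson-Hanson applies).
# Falls back to projected coordinate descent when Lawson-Hanson hits its
# iteration cap on near-degenerate systems.
nnls_fit <- function(A, b, prior = integer(0), prior_floor = 1e-12) {
  p <- ncol(A)
  if (p == 0L) return(numeric(0))
  if (length(prior)) b <- b - A[, prior, drop = FALSE] %*% rep(prior_floor, length(prior))
  b <- as.numeric(b)
  x <- tryCatch(pracma::lsqnonneg(A, b)$x,
                error = function(e) nnls_cd(A, b))
  if (length(prior)) x[prior] <- x[prior] + prior_floor
  x
}

nnls_cd <- function(A, b, max_sweeps = 2000L, tol = 1e-12) {
  p <- ncol(A)
  AtA <- crossprod(A)
  Atb <- as.numeric(crossprod(A, b))
  d <- diag(AtA)
  d[d <= 0] <- 1
  x <- numeric(p)
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_len(p)) {
      xj <- max(0, x[j] + (Atb[j] - sum(AtA[j, ] * x)) / d[j])
      delta <- max(delta, abs(xj - x[j]) * sqrt(d[j]))
      x[j] <- xj
    }
    if (delta < tol * (1 + sqrt(sum(Atb^2)))) break
  }
  x
}

rss_of <- function(A, b, k) {
  r <- if (length(k)) b - as.numeric(A %*% k) else b
  sum(r^2)
}

# RSS below relative machine precision of the response is an exact fit;
# flooring there keeps information criteria comparable between models that
# both fit to rounding error.
rss_floor <- function(b) max(.Machine$double.xmin, (1e-12 * sqrt(sum(b^2)))^2)

bic_of <- function(rss, n, s, floor_ = .Machine$double.xmin)
  n * log(max(rss, floor_) / n) + s * log(n)
aic_of <- function(rss, n, s, floor_ = .Machine$double.xmin)
  n * log(max(rss, floor_) / n) + 2 * s

#' Step 1: feasible generalized least squares reduction
#'
#' (1) A preliminary nonnegative least squares fit on the first-order
#' (mean) rows gives the order-of-magnitude estimate k_LS. (2) The
#' row-wise residual variance is modeled as
#' sigma^2_j = sd_b_j^2 + sum_l k_LS_l^2 sd_A_jl^2 (independent residual
#' components). (3) Rows of b and A are whitened by sigma^-1. (4) NNLS on
#' the whitened full system gives k_FG. (5) The support Phi keeps
#' coefficients above `support_threshold` relative to the largest (plus all
#' prior-knowledge reactions). (6) Adaptive penalty weights are the
#' magnitudes of the Moore-Penrose pseudoinverse solution of the whitened
#' system restricted to Phi, floored at 1e-12.
#'
#' @param sys a `regression_system`.
#' @param support_threshold relative support threshold tau (default 1e-6).
#' @param prior integer indices of prior-knowledge reactions (kept in Phi
#'   and constrained strictly positive in every fit).
#' @param kls_rows `"order1"` (default: fit k_LS on mean rows only) or
#'   `"all"`.
#' @param weight_source `"pinv"` (default) or `"fg"` (use k_FG magnitudes
#'   directly as adaptive weights).
#' @return an object of class `fg_result`: `k_ls`, `sigma_eps` (row SDs),
#'   `k_fg`, `support` (Phi), `weights` (k~ over Phi), and the whitened
#'   system `bS`, `AS`.
#' @export
step1_fg <- function(sys, support_threshold = 1e-6, prior = integer(0),
                     kls_rows = c("order1", "all"),
                     weight_source = c("pinv", "fg")) {
  kls_rows <- match.arg(kls_rows)
  weight_source <- match.arg(weight_source)
  stopifnot(inherits(sys, "regression_system"))
  ord1 <- moment_order(sys$row_target) == 1L
  rows1 <- if (kls_rows == "order1" && any(ord1)) which(ord1) else
    seq_along(sys$b)
  k_ls <- nnls_fit(sys$A[rows1, , drop = FALSE], sys$b[rows1], prior)
  sigma2 <- sys$sd_b^2 + as.numeric(sys$sd_A^2 %*% k_ls^2)
  if (any(sigma2 <= 0)) {
    pos <- sigma2[sigma2 > 0]
    floor_ <- if (length(pos)) min(pos) else 1
    warning(sum(sigma2 <= 0), " rows had zero residual-variance estimate; ",
            "floored at the smallest positive estimate", call. = FALSE)
    sigma2[sigma2 <= 0] <- floor_
  }
  w <- 1 / sqrt(sigma2)
  bS <- sys$b * w
  AS <- sys$A * w
  k_fg <- nnls_fit(AS, bS, prior)
  thr <- support_threshold * max(k_fg)
  support <- sort(union(which(k_fg > thr), prior))
  if (length(support) == 0L)
    stop("FG step selected an empty support (all coefficients zero)")
  weights <- if (weight_source == "pinv") {
    x <- as.numeric(pracma::pinv(AS[, support, drop = FALSE]) %*% bS)
    pmax(abs(x), 1e-12)
  } else pmax(k_fg[support], 1e-12)
  structure(list(k_ls = k_ls, sigma_eps = sqrt(sigma2), k_fg = k_fg,
                 support = support, weights = weights, bS = bS, AS = AS,
                 prior = prior),
            class = "fg_result")
}

# ADMM for min ||b - A k||^2 + lambda * sum(w_i k_i) subject to k >= lb.
# Under the nonnegativity constraint the weighted L1 penalty is linear.
# Penalty parameter rho = 1 with adaptive rescaling (factor 2 when the
# primal/dual residual ratio exceeds 10); absolute tolerance 1e-8, relative
# 1e-6, at most 1e4 iterations.
admm_wlasso <- function(A, b, w, lambda, lb = NULL, z0 = NULL, u0 = NULL,
                        rho = 1, abstol = 1e-8, reltol = 1e-6,
                        max_iter = 10000L) {
  p <- ncol(A)
  if (is.null(lb)) lb <- numeric(p)
  # precondition: scale the quadratic so rho = 1 matches the problem scale
  # (objective scaled by sc^2 with lambda scaled alike; argmin unchanged)
  sc <- sqrt(nrow(A) * p) / max(norm(A, "F"), .Machine$double.eps)
  A <- A * sc; b <- b * sc; lambda <- lambda * sc^2
  AtA2 <- 2 * crossprod(A)
  Atb2 <- 2 * as.numeric(crossprod(A, b))
  chol_f <- chol(AtA2 + rho * diag(p))
  z <- if (is.null(z0)) numeric(p) else z0
  u <- if (is.null(u0)) numeric(p) else u0
  converged <- FALSE
  iter <- 0L
  sp <- sqrt(p)
  for (iter in seq_len(max_iter)) {
    x <- backsolve(chol_f, backsolve(chol_f, Atb2 + rho * (z - u),
                                     transpose = TRUE))
    z_old <- z
    z <- pmax(lb, x + u - lambda * w / rho)
    u <- u + x - z
    r_norm <- sqrt(sum((x - z)^2))
    s_norm <- rho * sqrt(sum((z - z_old)^2))
    eps_pri <- sp * abstol + reltol * max(sqrt(sum(x^2)), sqrt(sum(z^2)))
    eps_dual <- sp * abstol + reltol * rho * sqrt(sum(u^2))
    if (r_norm < eps_pri && s_norm < eps_dual) { converged <- TRUE; break }
    if (r_norm > 10 * s_norm) {
      rho <- rho * 2; u <- u / 2
      chol_f <- chol(AtA2 + rho * diag(p))
    } else if (s_norm > 10 * r_norm) {
      rho <- rho / 2; u <- u * 2
      chol_f <- chol(AtA2 + rho * diag(p))
    }
  }
  list(k = z, converged = converged, iters = iter, rho = rho, u = u)
}

#' Step 2: adaptive relaxed lasso over a regularization path
#'
#' For each lambda on a decreasing grid, solves the nonnegative adaptive
#' lasso min ||bS - AS_Phi k||^2 + lambda sum_i k_i / k~_i by ADMM
#' (prior-knowledge reactions are unpenalized and floored strictly
#' positive), then removes shrinkage bias by a relaxed NNLS refit on the
#' active set. Five-fold cross-validation (rows stratified by moment block)
#' records per-fold selections for stability frequencies and held-out
#' prediction error; BIC is computed per lambda on the full-data relaxed
#' refit.
#'
#' @param fg an `fg_result` from [step1_fg()].
#' @param lambda optional decreasing lambda grid; by default `nlambda`
#'   log-spaced values from the analytic all-zero bound lambda_max down to
#'   lambda_max * 1e-6.
#' @param nlambda grid size (default 50).
#' @param folds number of cross-validation folds (default 5).
#' @param seed integer seed for the fold split.
#' @param L_full total library size (for the large-system BIC elbow rule in
#'   [select_model()]); defaults to the column count of the FG system.
#' @return an object of class `path_result`: `lambda`, relaxed `coef`
#'   (|Phi| x nlambda), `cv_error`, `stability` (nlambda x |Phi|), `bic`,
#'   `aic`, per-lambda `active` sets, ADMM convergence flags, plus the
#'   restricted system for downstream selection.
#' @export
step2_adaptive_relaxed_lasso <- function(fg, lambda = NULL, nlambda = 50L,
                                         folds = 5L, seed = 1L,
                                         L_full = NULL) {
  stopifnot(inherits(fg, "fg_result"))
  Phi <- fg$support
  ASF <- fg$AS[, Phi, drop = FALSE]
  bS <- fg$bS
  ktilde <- fg$weights
  prior_local <- match(intersect(fg$prior, Phi), Phi)
  pL <- length(Phi)
  w <- 1 / ktilde
  lb <- numeric(pL)
  if (length(prior_local)) { w[prior_local] <- 0; lb[prior_local] <- 1e-12 }

  if (is.null(lambda)) {
    corr <- pmax(as.numeric(crossprod(ASF, bS)), 0) * ktilde
    if (length(prior_local)) corr[prior_local] <- 0
    lmax <- 2 * max(corr)
    if (lmax <= 0) lmax <- 1
    lambda <- exp(seq(log(lmax), log(lmax * 1e-6), length.out = nlambda))
  }
  lambda <- sort(lambda, decreasing = TRUE)
  nl <- length(lambda)
  n <- length(bS)

  # stratified fold split: each moment block's rows spread across folds
  fold_id <- integer(n)
  with_seed(derive_seed(seed, "cvfolds"), {
    for (tgt in unique(row_block(fg))) {
      rows <- which(row_block(fg) == tgt)
      fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
  })

  run_path <- function(rows) {
    A_ <- ASF[rows, , drop = FALSE]; b_ <- bS[rows]
    act <- vector("list", nl); conv <- logical(nl)
    z0 <- NULL; u0 <- NULL
    for (i in seq_len(nl)) {
      fit <- admm_wlasso(A_, b_, w, lambda[i], lb = lb, z0 = z0, u0 = u0)
      z0 <- fit$k; u0 <- fit$u
      conv[i] <- fit$converged
      act[[i]] <- sort(union(which(fit$k > 1e-10), prior_local))
    }
    list(active = act, converged = conv)
  }

  full <- run_path(seq_len(n))
  if (any(!full$converged))
    warning(sum(!full$converged), " of ", nl,
            " ADMM fits did not converge within the iteration budget; ",
            "results retained", call. = FALSE)
  floor_ <- rss_floor(bS)
  coef <- matrix(0, pL, nl)
  bic <- numeric(nl); aic <- numeric(nl)
  for (i in seq_len(nl)) {
    a <- full$active[[i]]
    k <- nnls_fit(ASF[, a, drop = FALSE], bS,
                  prior = match(prior_local, a))
    coef[a, i] <- k
    rss <- rss_of(ASF[, a, drop = FALSE], bS, k)
    s <- sum(k > 0)
    bic[i] <- bic_of(rss, n, s, floor_)
    aic[i] <- aic_of(rss, n, s, floor_)
  }

  stability <- matrix(0, nl, pL)
  cv_sse <- numeric(nl)
  for (f in seq_len(folds)) {
    train <- which(fold_id != f); test <- which(fold_id == f)
    pf <- run_path(train)
    for (i in seq_len(nl)) {
      a <- pf$active[[i]]
      stability[i, a] <- stability[i, a] + 1 / folds
      kf <- nnls_fit(ASF[train, a, drop = FALSE], bS[train],
                     prior = match(prior_local, a))
      cv_sse[i] <- cv_sse[i] +
        rss_of(ASF[test, a, drop = FALSE], bS[test], kf)
    }
  }

  structure(list(lambda = lambda, coef = coef, cv_error = cv_sse / n,
                 stability = stability, bic = bic, aic = aic,
                 active = full$active, converged = full$converged,
                 support = Phi, prior_local = prior_local,
                 ASF = ASF, bS = bS,
                 L_full = if (is.null(L_full)) ncol(fg$AS) else L_full),
            class = "path_result")
}

row_block <- function(fg) attr(fg, "row_block") %||% rep("all", length(fg$bS))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Step 2 model selection: BIC, stability filter and backward refinement
#'
#' Picks lambda* minimizing the information criterion over the path (for
#' libraries larger than 1000 candidates, the documented elbow variant: the
#' sparsest model whose criterion lies within 1% of the total drop to the
#' minimum). The candidate set keeps active reactions whose stability
#' frequency across CV folds reaches `stability_threshold` (prior-knowledge
#' reactions are always kept), then backward stepwise refinement repeatedly
#' drops the reaction whose removal least increases the residual sum of
#' squares, accepting drops while the criterion does not increase.
#'
#' @param path a `path_result`.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param stability_threshold selection-frequency threshold pi in `[0, 1]`
#'   (default 0.8).
#' @return an object of class `selection_result`: `selected` (library
#'   reaction indices), `k_hat`, `lambda_star`, `bic_star`, `stability`
#'   (per selected reaction).
#' @export
select_model <- function(path, criterion = c("BIC", "AIC"),
                         stability_threshold = 0.8) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(path, "path_result"))
  if (length(path$lambda) == 0L) stop("empty regularization path")
  crit <- if (criterion == "BIC") path$bic else path$aic
  if (path$L_full > 1000L) {
    drop_tot <- max(crit) - min(crit)
    ok <- which(crit <= min(crit) + 0.01 * drop_tot)
    sizes <- vapply(path$active, length, 0L)[ok]
    istar <- ok[order(sizes, -ok)][1]   # sparsest, then largest lambda
  } else {
    istar <- which.min(crit)
  }
  act <- which(path$coef[, istar] > 0)
  act <- sort(union(act, path$prior_local))
  # per-reaction stability score: peak selection frequency across folds over
  # the path (the standard stability-selection statistic; frequency at one
  # grid point alone is brittle where a reaction enters the path)
  stab <- apply(path$stability, 2L, max)
  keep <- act[stab[act] >= stability_threshold | act %in% path$prior_local]
  if (length(keep) == 0L) keep <- path$prior_local
  n <- length(path$bS)
  crit_fun <- if (criterion == "BIC") bic_of else aic_of
  floor_ <- rss_floor(path$bS)

  refit <- function(set) {
    k <- nnls_fit(path$ASF[, set, drop = FALSE], path$bS,
                  prior = match(path$prior_local, set))
    rss <- rss_of(path$ASF[, set, drop = FALSE], path$bS, k)
    list(k = k, rss = rss, crit = crit_fun(rss, n, sum(k > 0), floor_))
  }
  cur <- refit(keep)
  repeat {
    droppable <- setdiff(keep, path$prior_local)
    if (length(droppable) == 0L || length(keep) <= 1L) break
    trials <- lapply(droppable, function(r) refit(setdiff(keep, r)))
    rsss <- vapply(trials, `[[`, numeric(1), "rss")
    best <- which.min(rsss)
    if (trials[[best]]$crit <= cur$crit) {
      keep <- setdiff(keep, droppable[best])
      cur <- trials[[best]]
    } else break
  }
  sel_global <- path$support[keep]
  structure(list(selected = sel_global, k_hat = setNames(cur$k, sel_global),
                 lambda_star = path$lambda[istar], bic_star = crit[istar],
                 criterion = criterion,
                 stability = setNames(stab[keep], sel_global)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("selected %d reactions (lambda* = %.3g, %s* = %.2f)\n",
              length(x$selected), x$lambda_star, x$criterion, x$bic_star))
  invisible(x)
}

#' Run the full two-step reactionet lasso on a regression system
#'
#' Convenience wrapper: [step1_fg()], [step2_adaptive_relaxed_lasso()],
#' [select_model()].
#'
#' @param sys a `regression_system`.
#' @param prior integer indices of prior-knowledge reactions.
#' @param support_threshold FG support threshold (default 1e-6).
#' @param nlambda,folds,seed,criterion,stability_threshold see the step
#'   functions.
#' @param kls_rows,weight_source see [step1_fg()].
#' @return a list with `fg`, `path` and `selection`.
#' @export
reactionet_lasso <- function(sys, prior = integer(0),
                             support_threshold = 1e-6, nlambda = 50L,
                             folds = 5L, seed = 1L, criterion = "BIC",
                             stability_threshold = 0.8,
                             kls_rows = "order1", weight_source = "pinv") {
  fg <- step1_fg(sys, support_threshold, prior, kls_rows, weight_source)
  attr(fg, "row_block") <- sys$row_target
  path <- step2_adaptive_relaxed_lasso(fg, nlambda = nlambda, folds = folds,
                                       seed = seed, L_full = sys$L)
  sel <- select_model(path, criterion, stability_threshold)
  list(fg = fg, path = path, selection = sel)
}
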