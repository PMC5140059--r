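# Central-moment equations for mass-action networks.
#
# A moment index is a multiset of species indices: length-1 indices are means
# mu_i, length-2 are second central moments C_ij (variances when i = j),
# length-3 are third central moments. Moment keys are canonical strings
# "M<i>", "M<i>.<j>", "M<i>.<j>.<k>" with sorted indices.
#
# The per-reaction contribution F_rl to dM_r/dt is represented as a
# polynomial over moment keys: a named numeric vector whose names are
# monomials (moment keys joined by "*", "1" for the constant term) and whose
# values are coefficients.

#' Canonical moment key for a multiset of species indices
#' @param idx integer vector of species indices (length 1..3).
#' @return a string key, e.g. `"M1"`, `"M1.2"`.
#' @export
moment_key <- function(idx) paste0("M", paste(sort(as.integer(idx)), collapse = "."))

#' Parse a moment key back into its species-index multiset
#' @param key a moment key string.
#' @return sorted integer vector.
#' @export
parse_moment_key <- function(key) as.integer(strsplit(sub("^M", "", key), ".", fixed = TRUE)[[1]])

#' Order of a moment key
#' @param key moment key string (vectorized).
#' @return integer order(s) 1..3.
#' @export
moment_order <- function(key) lengths(strsplit(sub("^M", "", key), ".", fixed = TRUE))

#' Canonical ordered moment basis
#'
#' Order-1 means first, then order-2 (variances C_ii, then covariances C_ij
#' with i < j), then (if `max_order = 3`) all order-3 multisets
#' lexicographically.
#'
#' @param n_species number of species N.
#' @param max_order 1, 2 or 3.
#' @return character vector of moment keys in canonical order.
#' @export
moment_basis <- function(n_species, max_order = 2L) {
  stopifnot(max_order %in% 1:3)
  n <- n_species
  keys <- paste0("M", seq_len(n))
  if (max_order >= 2L) {
    keys <- c(keys, vapply(seq_len(n), function(i) moment_key(c(i, i)), ""))
    if (n >= 2L)
      keys <- c(keys, apply(combn(n, 2L), 2L, function(p) moment_key(p)))
  }
  if (max_order >= 3L) {
    trip <- list()
    for (i in seq_len(n)) for (j in i:n) for (k in j:n)
      trip[[length(trip) + 1L]] <- moment_key(c(i, j, k))
    keys <- c(keys, unlist(trip))
  }
  keys
}

## --- tiny polynomial algebra over moment keys ------------------------------

poly_zero <- function() setNames(numeric(0), character(0))

mono_name <- function(keys) if (length(keys) == 0L) "1" else
  paste(sort(keys), collapse = "*")

poly_term <- function(coef, keys = character(0)) setNames(coef, mono_name(keys))

poly_add <- function(...) {
  ps <- list(...)
  all <- unlist(ps)
  if (length(all) == 0L) return(poly_zero())
  v <- tapply(unname(all), names(all), sum)
  v <- v[abs(v) > 1e-14]
  out <- setNames(as.numeric(v), names(v))
  out[order(names(out))]
}

poly_scale <- function(p, s) {
  if (s == 0 || length(p) == 0L) return(poly_zero())
  p * s
}

poly_is_zero <- function(p) length(p) == 0L

# E[g(X)] expanded in central moments, for the mass-action combinatorial
# factor g of a reactant multiset.
expectation_of_propensity <- function(reactants) {
  re <- sort(as.integer(reactants))
  if (length(re) == 0L) return(poly_term(1))                      # g = 1
  if (length(re) == 1L) return(poly_term(1, moment_key(re)))      # E[X_a]
  a <- re[1]; b <- re[2]
  if (a != b)  # E[X_a X_b] = mu_a mu_b + C_ab
    return(poly_add(poly_term(1, c(moment_key(a), moment_key(b))),
                    poly_term(1, moment_key(c(a, b)))))
  # E[X_a(X_a - 1)] = mu_a^2 + C_aa - mu_a
  poly_add(poly_term(1, c(moment_key(a), moment_key(a))),
           poly_term(1, moment_key(c(a, a))),
           poly_term(-1, moment_key(a)))
}

# Cov(X_j, g(X)) expanded in central moments (third central moments appear
# for bimolecular g).
cov_with_propensity <- function(j, reactants) {
  re <- sort(as.integer(reactants))
  if (length(re) == 0L) return(poly_zero())
  if (length(re) == 1L) return(poly_term(1, moment_key(c(j, re[1]))))
  a <- re[1]; b <- re[2]
  if (a != b)  # Cov(X_j, X_a X_b) = M_jab + mu_a C_jb + mu_b C_ja
    return(poly_add(poly_term(1, moment_key(c(j, a, b))),
                    poly_term(1, c(moment_key(a), moment_key(c(j, b)))),
                    poly_term(1, c(moment_key(b), moment_key(c(j, a))))))
  # Cov(X_j, X_a(X_a-1)) = M_jaa + 2 mu_a C_ja - C_ja
  poly_add(poly_term(1, moment_key(c(j, a, a))),
           poly_term(2, c(moment_key(a), moment_key(c(j, a)))),
           poly_term(-1, moment_key(c(j, a))))
}

#' Derive the central-moment equations of a mass-action network
#'
#' For every target moment of order up to `max_order` and every reaction l,
#' computes the stoichiometric moment function F_rl such that
#' dM_r/dt = sum_l k_l F_rl(M). Means use F = s_li E[g_l]; second central
#' moments use F = s_li Cov(X_j, g_l) + s_lj Cov(X_i, g_l) + s_li s_lj E[g_l],
#' with all expectations expanded about the mean. Polynomials are expanded,
#' simplified and canonically ordered; reactions contributing zero to a
#' target are omitted.
#'
#' @param x a `reaction_network` or `candidate_library`.
#' @param max_order highest order of target moments, 1 or 2.
#' @return an object of class `moment_equations`: targets (moment keys),
#'   number of reactions `L`, and `F[[target]][[as.character(l)]]`
#'   polynomials.
#' @export
derive_moment_equations <- function(x, max_order = 2L) {
  if (inherits(x, "candidate_library")) x <- x$network
  stopifnot(inherits(x, "reaction_network"), max_order %in% 1:2)
  n <- length(x$species)
  targets <- moment_basis(n, max_order)
  L <- length(x$reactions)
  Fmap <- setNames(vector("list", length(targets)), targets)
  for (t in targets) Fmap[[t]] <- list()
  for (l in seq_len(L)) {
    r <- x$reactions[[l]]
    if (length(r$reactants) > 2L)
      stop("unsupported propensity degree (more than two reactant molecules)")
    s <- stoichiometry_vector(r, n)
    Eg <- expectation_of_propensity(r$reactants)
    touched <- which(s != 0L)
    for (i in touched) {
      p <- poly_scale(Eg, s[i])
      if (!poly_is_zero(p)) Fmap[[moment_key(i)]][[as.character(l)]] <- p
    }
    if (max_order >= 2L) {
      covs <- lapply(seq_len(n), function(j) cov_with_propensity(j, r$reactants))
      for (i in seq_len(n)) for (j in i:n) {
        if (s[i] == 0L && s[j] == 0L) next
        p <- poly_add(poly_scale(covs[[j]], s[i]),
                      poly_scale(covs[[i]], s[j]),
                      poly_scale(Eg, s[i] * s[j]))
        if (!poly_is_zero(p))
          Fmap[[moment_key(c(i, j))]][[as.character(l)]] <- p
      }
    }
  }
  structure(list(species = x$species, n_species = n, L = L,
                 max_order = as.integer(max_order),
                 targets = targets, F = Fmap),
            class = "moment_equations")
}

#' Moment indices required to evaluate a set of moment equations
#'
#' The exact set of moment keys appearing in any stoichiometric moment
#' function polynomial; at most order 2 when all propensities are linear, up
#' to order 3 when any bimolecular propensity is present.
#'
#' @param eqs a `moment_equations` object.
#' @return character vector of moment keys (canonically sorted).
#' @export
required_input_moments <- function(eqs) {
  keys <- character(0)
  for (t in eqs$targets) for (p in eqs$F[[t]]) {
    nm <- names(p)
    nm <- nm[nm != "1"]
    if (length(nm)) keys <- c(keys, unlist(strsplit(nm, "*", fixed = TRUE)))
  }
  sort(unique(keys))
}

#' Evaluate one stoichiometric moment function
#'
#' @param f a polynomial over moment keys (as stored in
#'   `moment_equations$F`).
#' @param moments named numeric vector of moment values keyed by moment key.
#' @return the polynomial value.
#' @export
evaluate_design_entry <- function(f, moments) {
  if (length(f) == 0L) return(0)
  val <- 0
  for (i in seq_along(f)) {
    mono <- names(f)[i]
    if (mono == "1") { val <- val + f[[i]]; next }
    keys <- strsplit(mono, "*", fixed = TRUE)[[1]]
    miss <- setdiff(keys, names(moments))
    if (length(miss))
      stop("missing moment value for index ", miss[1])
    val <- val + f[[i]] * prod(moments[keys])
  }
  val
}

#' Precompile a fast design-matrix evaluator
#'
#' Collects every monomial appearing in the moment equations into a sparse
#' coefficient matrix so that, given the moment values at one time point,
#' the full (targets x reactions) block of stoichiometric moment function
#' values is a single sparse matrix-vector product.
#'
#' @param eqs a `moment_equations` object.
#' @return an object of class `design_evaluator`.
#' @export
design_evaluator <- function(eqs) {
  targets <- eqs$targets
  nt <- length(targets); L <- eqs$L
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  mono_idx <- new.env(parent = emptyenv())
  monos <- character(0)
  for (ti in seq_along(targets)) {
    fl <- eqs$F[[targets[ti]]]
    for (lname in names(fl)) {
      l <- as.integer(lname)
      p <- fl[[lname]]
      row <- (l - 1L) * nt + ti
      for (k in seq_along(p)) {
        mono <- names(p)[k]
        mi <- mono_idx[[mono]]
        if (is.null(mi)) {
          monos <- c(monos, mono)
          mi <- length(monos)
          assign(mono, mi, envir = mono_idx)
        }
        ii <- c(ii, row); jj <- c(jj, mi); vv <- c(vv, p[[k]])
      }
    }
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nt * L, length(monos)))
  factors <- lapply(monos, function(m) {
    if (m == "1") character(0) else strsplit(m, "*", fixed = TRUE)[[1]]
  })
  needed <- sort(unique(unlist(factors)))
  structure(list(P = P, factors = factors, targets = targets, L = L,
                 needed = needed),
            class = "design_evaluator")
}

#' Evaluate the design block at one time point
#' @param ev a `design_evaluator`.
#' @param moments named numeric vector of moment values covering
#'   `ev$needed`.
#' @return numeric matrix (targets x reactions) of F values.
#' @export
eval_design <- function(ev, moments) {
  miss <- setdiff(ev$needed, names(moments))
  if (length(miss)) stop("missing moment value for index ", miss[1])
  mv <- vapply(ev$factors, function(f) if (length(f) == 0L) 1 else
    prod(moments[f]), numeric(1))
  matrix(as.numeric(ev$P %*% mv), nrow = length(ev$targets), ncol = ev$L)
}

#' Export moment equations as a readable text report
#'
#' One line per (target, reaction) pair with the polynomial spelled out; for
#' inspection and debugging.
#'
#' @param eqs a `moment_equations` object.
#' @param path optional file path; when NULL the lines are returned.
#' @return character vector of report lines, invisibly when written.
#' @export
moment_equation_report <- function(eqs, path = NULL) {
  fmt_poly <- function(p) {
    if (length(p) == 0L) return("0")
    paste(vapply(seq_along(p), function(i) {
      co <- p[[i]]; mono <- names(p)[i]
      term <- if (mono == "1") format(co) else
        if (co == 1) mono else if (co == -1) paste0("-", mono) else
          paste0(format(co), "*", mono)
      term
    }, ""), collapse = " + ")
  }
  lines <- character(0)
  for (t in eqs$targets) {
    fl <- eqs$F[[t]]
    for (lname in names(fl))
      lines <- c(lines, sprintf("d%s/dt  <- k%s * (%s)", t, lname,
                                fmt_poly(fl[[lname]])))
  }
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}
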