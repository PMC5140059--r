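# Scoring recovered networks against ground truth and reconstructing mean
# dynamics from recovered models.

# Matching key: exact (reactants, products) identity, except that
# conversions A -> B are matched irrespective of direction (the library
# enumerates one canonical direction per unordered pair).
match_key <- function(r) {
  if (length(r$reactants) == 1L && length(r$products) == 1L) {
    pair <- sort(c(r$reactants, r$products))
    return(paste0("conv:", pair[1], "~", pair[2]))
  }
  reaction_key(r)
}

#' Confusion counts of a recovered reaction set against ground truth
#'
#' True positives are exact (reactants, products) matches; conversion
#' candidates match irrespective of the canonical direction chosen at
#' enumeration.
#'
#' @param selected list of `rn_reaction` (the recovered set).
#' @param truth list of `rn_reaction` (the ground-truth set).
#' @param known optional list of `rn_reaction` flagged as prior knowledge.
#' @return an object of class `rn_confusion`: `tp`, `fp`, `fn`, `tp_known`.
#' @export
confusion <- function(selected, truth, known = list()) {
  sk <- vapply(selected, match_key, "")
  tk <- vapply(truth, match_key, "")
  kk <- vapply(known, match_key, "")
  sk <- unique(sk); tk <- unique(tk)
  tp_keys <- intersect(sk, tk)
  structure(list(tp = length(tp_keys),
                 fp = length(setdiff(sk, tk)),
                 fn = length(setdiff(tk, sk)),
                 tp_known = length(intersect(tp_keys, kk))),
            class = "rn_confusion")
}

#' @export
print.rn_confusion <- function(x, ...) {
  cat(sprintf("TP %d (%d known)  FP %d  FN %d\n",
              x$tp, x$tp_known, x$fp, x$fn))
  invisible(x)
}

#' True/false-positive tradeoff along a regularization path
#'
#' For each lambda on the path, scores the active reaction set against the
#' ground truth; suitable for overlaying paths across replicates.
#'
#' @param path a `path_result`.
#' @param library the `candidate_library` the path was fit over.
#' @param truth list of ground-truth `rn_reaction`.
#' @return a data.frame with columns `lambda`, `n_active`, `tp`, `fp`, `fn`.
#' @export
path_tradeoff <- function(path, library, truth) {
  rxns <- library$network$reactions
  known <- rxns[library$known]
  rows <- lapply(seq_along(path$lambda), function(i) {
    act_global <- path$support[path$active[[i]]]
    cf <- confusion(rxns[act_global], truth, known)
    data.frame(lambda = path$lambda[i], n_active = length(act_global),
               tp = cf$tp, fp = cf$fp, fn = cf$fn, tp_known = cf$tp_known)
  })
  do.call(rbind, rows)
}

#' Reconstruct mean trajectories from a recovered model
#'
#' Integrates the deterministic first-order mass-action mean equations
#' d mu / dt = sum_l k_l s_l g_l(mu) on the requested grid (a first-order
#' closure: the recovered model's exact mean dynamics would couple to second
#' moments for bimolecular reactions).
#'
#' @param network a `reaction_network` with rates set (e.g. the selected
#'   model with its rate estimates).
#' @param x0 initial mean counts (length N).
#' @param t_grid output time grid.
#' @param observed optional matrix (N x T) of observed means for RMSE
#'   reporting.
#' @return a list with `times`, `means` (N x T matrix) and, when `observed`
#'   is given, per-species `rmse`.
#' @export
reconstruct_means <- function(network, x0, t_grid, observed = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  n <- length(network$species)
  rates <- vapply(network$reactions, `[[`, numeric(1), "rate")
  if (length(rates) && (anyNA(rates) || any(rates < 0)))
    stop("all reactions need nonnegative rates for reconstruction")
  smat <- if (length(network$reactions))
    vapply(network$reactions, stoichiometry_vector, integer(n), n) else
      matrix(0, n, 0)
  gfuns <- lapply(network$reactions, mass_action_propensity)
  deriv <- function(t, y, parms) {
    g <- vapply(gfuns, function(f) f(y), numeric(1))
    list(as.numeric(smat %*% (rates * g)))
  }
  sol <- deSolve::ode(y = as.numeric(x0), times = t_grid, func = deriv,
                      parms = NULL)
  if (attr(sol, "istate")[1] < 0)
    stop("mean-equation integration failed: ", attr(sol, "istate")[1])
  means <- t(unname(sol[, -1, drop = FALSE]))
  rownames(means) <- network$species
  out <- list(times = t_grid, means = means)
  if (!is.null(observed))
    out$rmse <- sqrt(rowMeans((means - observed)^2))
  out
}

#' Extract the selected reactions as a rated network
#'
#' @param sel a `selection_result`.
#' @param library the `candidate_library` the selection indexes into.
#' @return a `reaction_network` whose reactions carry the estimated rates.
#' @export
selected_network <- function(sel, library) {
  rxns <- lapply(seq_along(sel$selected), function(i) {
    r <- library$network$reactions[[sel$selected[i]]]
    reaction(r$reactants, r$products, unname(sel$k_hat[i]))
  })
  reaction_network(library$network$species, rxns)
}
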