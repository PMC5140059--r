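# Run configuration, the end-to-end inference pipeline, and the file-based
# command layer the CLI script wraps.

#' Run the full inference pipeline on snapshot data
#'
#' Moments, noise correction, gradient matching and bootstrap variability
#' per replicate; replicate systems are concatenated and passed through the
#' two-step reactionet lasso.
#'
#' @param snapshots a `snapshot_series` or a list of replicate series (all
#'   over the same species, with `noise_p` set if noise-corrupted).
#' @param library a `candidate_library` over the same species.
#' @param orders `"2"` (moment equations up to order two) or `"1"` (means
#'   only).
#' @param gradient_method `"spline"`, `"fds"` or `"smooth"`.
#' @param B bootstrap replicates (default 200).
#' @param nlambda,folds,stability_threshold,criterion selection settings
#'   (see [step2_adaptive_relaxed_lasso()] and [select_model()]).
#' @param prior integer indices of prior-knowledge reactions in the library
#'   (defaults to the library's `known` mask).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param window smoothing window for the `"smooth"` gradient method.
#' @param trajectories dense-grid series (or list per replicate) for
#'   `"smooth"`.
#' @param verbose log stage progress to stderr.
#' @return a list with `library`, `eqs`, `sys`, `fg`, `path`, `selection`.
#' @export
infer_network <- function(snapshots, library, orders = "2",
                          gradient_method = "spline", B = 200L,
                          nlambda = 50L, folds = 5L,
                          stability_threshold = 0.8, criterion = "BIC",
                          prior = NULL, seed = 1L, window = 5L,
                          trajectories = NULL, verbose = FALSE) {
  if (inherits(snapshots, "snapshot_series")) snapshots <- list(snapshots)
  if (!is.null(trajectories) && inherits(trajectories, "snapshot_series"))
    trajectories <- list(trajectories)
  stopifnot(inherits(library, "candidate_library"))
  if (is.null(prior)) prior <- which(library$known)
  eqs <- derive_moment_equations(library,
                                 max_order = if (orders == "2") 2L else 1L)
  rn_log("derived moment equations: %d targets x %d reactions",
         length(eqs$targets), eqs$L, verbose = verbose)
  systems <- lapply(seq_along(snapshots), function(i) {
    s <- snapshots[[i]]
    boot <- bootstrap_variability(
      s, eqs, B = B, seed = derive_seed(seed, "bootstrap", i),
      gradient_method = gradient_method,
      trajectories = if (!is.null(trajectories)) trajectories[[i]],
      window = window)
    rn_log("replicate %d: bootstrap done (B = %d)", i, B, verbose = verbose)
    m <- structure(list(times = s$times, values = boot$point$moments,
                        n_cells = vapply(s$counts, nrow, 0L),
                        noise_p = NULL, species = s$species),
                   class = "moment_series")
    g <- structure(list(times = s$times, values = boot$point$gradients,
                        method = gradient_method),
                   class = "gradient_series")
    assemble_system(eqs, m, g, boot, orders = orders)
  })
  sys <- concat_replicates(systems)
  rn_log("regression system: %d rows x %d candidates", length(sys$b), sys$L,
         verbose = verbose)
  res <- reactionet_lasso(sys, prior = prior, nlambda = nlambda,
                          folds = folds, seed = derive_seed(seed, "cv"),
                          criterion = criterion,
                          stability_threshold = stability_threshold)
  rn_log("step 1 support |Phi| = %d; selected %d reactions",
         length(res$fg$support), length(res$selection$selected),
         verbose = verbose)
  c(list(library = library, eqs = eqs, sys = sys), res)
}

#' Read and validate a run configuration
#'
#' YAML fields: `network` (path to a network spec), `time_points`
#' (`scheme: uniform` with `n_points` and `t_max`, or `scheme: explicit` with
#' `points`), `n_cells`, `replicates`, `capture_p`, `gradient_method`,
#' `orders`, `bootstrap_B`, `nlambda`, `folds`, `stability_threshold`,
#' `criterion`, `prior_reactions` (list of `{reactants, products}` by
#' species name), `seed`, `outdir`. Every field is validated before any
#' compute; defaults fill the optional ones.
#'
#' @param path YAML config path.
#' @return a validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(replicates = 1L, capture_p = 1, gradient_method = "spline",
                   orders = "2", bootstrap_B = 200L, nlambda = 50L,
                   folds = 5L, stability_threshold = 0.8, criterion = "BIC",
                   seed = 1L, outdir = ".", window = 5L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$network)) stop("config: 'network' path is required")
  if (is.null(cfg$n_cells) || cfg$n_cells < 2) stop("config: n_cells >= 2 required")
  if (!(cfg$capture_p > 0 && cfg$capture_p <= 1))
    stop("config: capture_p must be in (0, 1]")
  if (!cfg$gradient_method %in% c("spline", "fds", "smooth"))
    stop("config: unknown gradient_method ", cfg$gradient_method)
  if (!as.character(cfg$orders) %in% c("1", "2"))
    stop("config: orders must be 1 or 2")
  cfg$orders <- as.character(cfg$orders)
  if (is.null(cfg$time_points)) stop("config: 'time_points' block is required")
  tp <- cfg$time_points
  if (identical(tp$scheme, "uniform")) {
    if (is.null(tp$n_points) || is.null(tp$t_max))
      stop("config: uniform time_points need n_points and t_max")
    cfg$t_grid <- select_time_points(c(0, tp$t_max), "uniform", n = tp$n_points)
  } else if (identical(tp$scheme, "explicit")) {
    pts <- as.numeric(unlist(tp$points))
    cfg$t_grid <- select_time_points(range(pts), "explicit", points = pts)
  } else stop("config: time_points scheme must be 'uniform' or 'explicit'")
  if (cfg$bootstrap_B < 50) stop("config: bootstrap_B must be >= 50")
  structure(cfg, class = "run_config")
}

resolve_prior <- function(cfg, spec, library) {
  if (is.null(cfg$prior_reactions)) return(integer(0))
  keys <- vapply(library$network$reactions, reaction_key, "")
  sp <- library$network$species
  idx <- vapply(cfg$prior_reactions, function(x) {
    r <- reaction(match(as.character(unlist(x$reactants)), sp),
                  match(as.character(unlist(x$products)), sp))
    i <- match(reaction_key(r), keys)
    if (is.na(i)) stop("prior reaction not in candidate library: ",
                       format_reaction(r, sp))
    i
  }, 0L)
  sort(unique(idx))
}

write_run_metadata <- function(cfg, path, extra = list()) {
  meta <- c(unclass(cfg), extra,
            list(package_version = as.character(utils::packageVersion("reactionet"))))
  meta$t_grid <- as.numeric(meta$t_grid)
  yaml::write_yaml(meta, path)
  invisible(path)
}

#' Simulate snapshot replicates from a run configuration
#'
#' Writes one snapshot table per replicate (with binomial noise applied when
#' `capture_p < 1`) plus a run-metadata file into `outdir`.
#'
#' @param cfg a `run_config` (see [read_run_config()]).
#' @param verbose log progress.
#' @return character vector of snapshot file paths, invisibly.
#' @export
cmd_simulate <- function(cfg, verbose = FALSE) {
  spec <- read_network_spec(cfg$network)
  rates <- vapply(spec$network$reactions, `[[`, numeric(1), "rate")
  if (anyNA(rates)) stop("network spec must carry rates for simulation")
  x0 <- if (!is.null(cfg$x0)) as.integer(unlist(cfg$x0)) else
    stop("config: 'x0' initial counts are required for simulation")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    s <- ssa_simulate(spec$network, x0, cfg$t_grid, cfg$n_cells,
                      seed = derive_seed(cfg$seed, "ssa", r))
    if (cfg$capture_p < 1)
      s <- apply_binomial_noise(s, cfg$capture_p,
                                seed = derive_seed(cfg$seed, "noise", r))
    s$replicate_id <- r
    paths[r] <- file.path(cfg$outdir, sprintf("snapshots_rep%02d.tsv", r))
    write_snapshots(s, paths[r])
    rn_log("wrote %s (%d cells x %d time points)", paths[r], cfg$n_cells,
           length(cfg$t_grid), verbose = verbose)
  }
  write_run_metadata(cfg, file.path(cfg$outdir, "run_metadata.yaml"),
                     list(stage = "simulate", snapshot_files = paths))
  invisible(paths)
}

#' Infer a reaction network from snapshot files
#'
#' Reads the snapshot tables, builds the candidate library from the network
#' spec's species (honoring modules and cross-module reactions), runs the
#' full pipeline and writes the per-lambda path table, the final-model table
#' and run metadata into `outdir`.
#'
#' @param cfg a `run_config`.
#' @param snapshot_files paths written by [cmd_simulate()] (defaults to the
#'   standard names under `outdir`).
#' @param verbose log stage progress.
#' @return the [infer_network()] result, invisibly.
#' @export
cmd_infer <- function(cfg, snapshot_files = NULL, verbose = FALSE) {
  spec <- read_network_spec(cfg$network)
  if (is.null(snapshot_files))
    snapshot_files <- file.path(cfg$outdir,
                                sprintf("snapshots_rep%02d.tsv",
                                        seq_len(cfg$replicates)))
  for (f in snapshot_files) if (!file.exists(f)) stop("missing snapshot file: ", f)
  snaps <- lapply(seq_along(snapshot_files), function(i)
    read_snapshots(snapshot_files[i],
                   noise_p = if (cfg$capture_p < 1) cfg$capture_p,
                   replicate_id = i))
  library <- enumerate_candidates(spec$network$species,
                                  modules = spec$modules,
                                  cross_reactions = spec$cross_module_reactions)
  prior <- resolve_prior(cfg, spec, library)
  res <- infer_network(snaps, library, orders = cfg$orders,
                       gradient_method = cfg$gradient_method,
                       B = cfg$bootstrap_B, nlambda = cfg$nlambda,
                       folds = cfg$folds,
                       stability_threshold = cfg$stability_threshold,
                       criterion = cfg$criterion, prior = prior,
                       seed = cfg$seed, window = cfg$window,
                       verbose = verbose)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_path_table(res$path, res$library,
                   file.path(cfg$outdir, "path.tsv"))
  write_model_table(res$selection, res$library,
                    file.path(cfg$outdir, "final_model.tsv"))
  write_run_metadata(cfg, file.path(cfg$outdir, "run_metadata.yaml"),
                     list(stage = "infer", n_rows = length(res$sys$b),
                          support_size = length(res$fg$support)))
  rn_log("inference done: %d reactions selected", length(res$selection$selected),
         verbose = verbose)
  invisible(res)
}

#' Write the per-lambda path table
#' @param path a `path_result`.
#' @param library the candidate library.
#' @param file output path (tab-separated).
#' @return `file`, invisibly.
#' @export
write_path_table <- function(path, library, file) {
  sp <- library$network$species
  rows <- list()
  for (i in seq_along(path$lambda)) {
    a <- path$active[[i]]
    if (length(a) == 0L) next
    gl <- path$support[a]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      lambda = path$lambda[i], reaction = gl,
      formula = vapply(library$network$reactions[gl],
                       format_reaction, "", sp),
      coefficient = path$coef[a, i],
      cv_error = path$cv_error[i],
      stability_freq = path$stability[i, a],
      bic = path$bic[i])
  }
  dt <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(lambda = numeric(0), reaction = integer(0),
                           formula = character(0), coefficient = numeric(0),
                           cv_error = numeric(0), stability_freq = numeric(0),
                           bic = numeric(0))
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' Write the final-model table
#' @param sel a `selection_result`.
#' @param library the candidate library.
#' @param file output path (tab-separated).
#' @return `file`, invisibly.
#' @export
write_model_table <- function(sel, library, file) {
  sp <- library$network$species
  rxns <- library$network$reactions[sel$selected]
  dt <- data.table::data.table(
    reaction = sel$selected,
    reactants = vapply(rxns, function(r) paste(sp[r$reactants], collapse = "+"), ""),
    products = vapply(rxns, function(r) paste(sp[r$products], collapse = "+"), ""),
    k_hat = as.numeric(sel$k_hat),
    stability_freq = as.numeric(sel$stability))
  data.table::fwrite(dt, file, sep = "\t")
  invisible(file)
}

#' Score an inference result against a ground-truth network spec
#'
#' Writes confusion counts, the regularization-path tradeoff table and (when
#' `x0` is available in the config) mean-trajectory RMSE reports.
#'
#' @param res an [infer_network()] result.
#' @param truth_spec path to the ground-truth network YAML.
#' @param outdir output directory.
#' @param observed_means optional N x T matrix of observed means for the
#'   reconstruction report.
#' @param x0,t_grid initial counts and grid for mean reconstruction.
#' @return the `rn_confusion`, invisibly.
#' @export
cmd_evaluate <- function(res, truth_spec, outdir = ".",
                         observed_means = NULL, x0 = NULL, t_grid = NULL) {
  if (!file.exists(truth_spec)) stop("missing truth spec: ", truth_spec)
  truth <- read_network_spec(truth_spec)
  if (!identical(truth$network$species, res$library$network$species))
    stop("truth and library species orderings differ")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sel_rxns <- res$library$network$reactions[res$selection$selected]
  known <- res$library$network$reactions[res$library$known]
  cf <- confusion(sel_rxns, truth$network$reactions, known)
  data.table::fwrite(data.table::data.table(
    tp = cf$tp, fp = cf$fp, fn = cf$fn, tp_known = cf$tp_known),
    file.path(outdir, "confusion.tsv"), sep = "\t")
  to <- path_tradeoff(res$path, res$library, truth$network$reactions)
  data.table::fwrite(to, file.path(outdir, "tradeoff.tsv"), sep = "\t")
  if (!is.null(x0) && !is.null(t_grid)) {
    net <- selected_network(res$selection, res$library)
    rec <- reconstruct_means(net, x0, t_grid, observed = observed_means)
    data.table::fwrite(data.table::data.table(
      species = res$library$network$species,
      rmse = if (is.null(rec$rmse)) NA_real_ else as.numeric(rec$rmse)),
      file.path(outdir, "reconstruction_rmse.tsv"), sep = "\t")
  }
  invisible(cf)
}

#' Simulate-infer-evaluate pipeline from one configuration
#' @param cfg a `run_config` whose network spec carries ground-truth rates.
#' @param verbose log stage progress.
#' @return the inference result, invisibly.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  files <- cmd_simulate(cfg, verbose = verbose)
  res <- cmd_infer(cfg, files, verbose = verbose)
  cmd_evaluate(res, cfg$network, outdir = cfg$outdir)
  invisible(res)
}
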