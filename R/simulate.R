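#' Construct a snapshot time series container
#'
#' Per-time-point matrices of per-cell species counts. Cells are independent
#' realizations; the estimators never track cells across time points
#' (snapshot, not trajectory, data model).
#'
#' @param times increasing numeric vector of time points.
#' @param counts list of integer matrices (cells x species), one per time
#'   point, all with the same column count.
#' @param species character vector of species names.
#' @param noise_p capture efficiency in (0, 1] if the counts are
#'   noise-corrupted, else NULL.
#' @param replicate_id integer replicate label.
#' @return an object of class `snapshot_series`.
#' @export
snapshot_series <- function(times, counts, species, noise_p = NULL,
                            replicate_id = 1L) {
  stopifnot(length(times) == length(counts), !is.unsorted(times, strictly = TRUE))
  for (m in counts) {
    stopifnot(is.matrix(m), ncol(m) == length(species))
    if (nrow(m) < 2L) stop("each snapshot needs at least 2 cells")
    if (any(m < 0)) stop("counts must be nonnegative")
  }
  structure(list(times = as.numeric(times), counts = counts,
                 species = as.character(species), noise_p = noise_p,
                 replicate_id = as.integer(replicate_id)),
            class = "snapshot_series")
}

#' @export
print.snapshot_series <- function(x, ...) {
  cat(sprintf("snapshot series: %d species, %d time points, %s cells/time%s\n",
              length(x$species), length(x$times),
              paste(unique(vapply(x$counts, nrow, 0L)), collapse = "/"),
              if (is.null(x$noise_p)) "" else
                sprintf(", capture efficiency p = %g", x$noise_p)))
  invisible(x)
}

#' Simulate single-cell snapshot ensembles with the Gillespie algorithm
#'
#' Each cell is an independent exact realization of the network's Chemical
#' Master Equation dynamics (direct-method stochastic simulation algorithm),
#' sampled at the requested time grid. Identical inputs and seed give
#' bit-identical output; enlarging `n_cells` leaves earlier cells unchanged.
#'
#' @param network a `reaction_network` with all rates set.
#' @param x0 initial counts: an integer vector of length N (deterministic
#'   initial condition for every cell), or a list
#'   `list(mean = <vector>, sampler = "poisson")` for Poisson-dispersed
#'   initial conditions.
#' @param t_grid increasing nonnegative time vector at which snapshots are
#'   taken.
#' @param n_cells ensemble size (number of cells).
#' @param seed integer seed.
#' @param keep_trajectories when TRUE, additionally record the ensemble on a
#'   dense grid of `dense_n` points spanning the same interval (used only by
#'   the "smooth" oracle gradient estimator).
#' @param dense_n dense-grid size for `keep_trajectories`.
#' @return a `snapshot_series`; with `keep_trajectories`, the attribute
#'   `"trajectories"` holds the dense-grid `snapshot_series`.
#' @export
ssa_simulate <- function(network, x0, t_grid, n_cells, seed = 1L,
                         keep_trajectories = FALSE, dense_n = 101L) {
  stopifnot(inherits(network, "reaction_network"))
  rates <- vapply(network$reactions, `[[`, numeric(1), "rate")
  if (anyNA(rates) || any(rates < 0))
    stop("all reactions must carry nonnegative rates for simulation")
  t_grid <- as.numeric(t_grid)
  if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid < 0))
    stop("t_grid must be strictly increasing and nonnegative")
  n <- length(network$species)

  if (is.list(x0)) {
    mu <- as.numeric(x0$mean)
    stopifnot(length(mu) == n, all(mu >= 0))
    sampler <- if (is.null(x0$sampler)) "poisson" else x0$sampler
    if (sampler != "poisson") stop("unknown x0 sampler: ", sampler)
    x0m <- with_seed(derive_seed(seed, "x0"),
                     matrix(rpois(n_cells * n, rep(mu, each = n_cells)),
                            n_cells, n))
  } else {
    x0 <- as.integer(x0)
    stopifnot(length(x0) == n)
    if (any(x0 < 0)) stop("initial counts must be nonnegative")
    x0m <- matrix(rep(x0, each = n_cells), n_cells, n)
  }
  storage.mode(x0m) <- "integer"

  L <- length(network$reactions)
  pad2 <- function(v) { v <- as.integer(v) - 1L; c(v, rep(-1L, 2L - length(v)))[1:2] }
  rm_ <- if (L) t(vapply(network$reactions, function(r) pad2(r$reactants),
                         integer(2))) else matrix(integer(0), 0, 2)
  pm_ <- if (L) t(vapply(network$reactions, function(r) pad2(r$products),
                         integer(2))) else matrix(integer(0), 0, 2)

  grid <- t_grid
  if (keep_trajectories) {
    dense <- seq(min(c(0, t_grid)), max(t_grid), length.out = dense_n)
    grid <- sort(unique(c(t_grid, dense)))
  }
  snaps <- ssa_simulate_cpp(rm_, pm_, rates, x0m, grid, as.integer(seed))
  names(snaps) <- NULL
  pick <- function(tt) {
    idx <- match(tt, grid)
    lapply(idx, function(i) {
      m <- snaps[[i]]; colnames(m) <- network$species; m
    })
  }
  out <- snapshot_series(t_grid, pick(t_grid), network$species)
  if (keep_trajectories)
    attr(out, "trajectories") <- snapshot_series(dense, pick(dense),
                                                 network$species)
  out
}

#' Corrupt snapshots with binomial capture-efficiency noise
#'
#' Every count X is independently replaced by a Binomial(X, p) draw,
#' emulating a single-cell instrument that detects each molecule with
#' probability p.
#'
#' @param s a noise-free `snapshot_series`.
#' @param p capture efficiency in (0, 1].
#' @param seed integer seed.
#' @return a `snapshot_series` with `noise_p = p`.
#' @export
apply_binomial_noise <- function(s, p, seed = 1L) {
  stopifnot(inherits(s, "snapshot_series"))
  if (!is.null(s$noise_p)) stop("snapshots are already noise-corrupted")
  if (!(p > 0 && p <= 1)) stop("capture efficiency p must be in (0, 1]")
  counts <- with_seed(derive_seed(seed, "binomial_noise"), lapply(s$counts, function(m) {
    out <- matrix(rbinom(length(m), size = as.vector(m), prob = p),
                  nrow(m), ncol(m))
    colnames(out) <- colnames(m)
    out
  }))
  snapshot_series(s$times, counts, s$species, noise_p = p,
                  replicate_id = s$replicate_id)
}

#' Select measurement time points from a dense span
#'
#' @param t_dense numeric vector whose range defines the admissible span.
#' @param scheme `"uniform"` for `n` equally spaced points including both
#'   endpoints, or `"explicit"` to pass `points` through (sorted).
#' @param n number of points for the uniform scheme (>= 3).
#' @param points explicit time points (within the span).
#' @return numeric time vector.
#' @export
select_time_points <- function(t_dense, scheme = c("uniform", "explicit"),
                               n = 13L, points = NULL) {
  scheme <- match.arg(scheme)
  lo <- min(t_dense); hi <- max(t_dense)
  if (scheme == "uniform") {
    if (n < 3L) stop("at least 3 time points are required for gradient estimation")
    return(seq(lo, hi, length.out = n))
  }
  points <- sort(as.numeric(points))
  if (length(points) < 3L) stop("at least 3 time points are required for gradient estimation")
  if (min(points) < lo || max(points) > hi)
    stop("explicit time points fall outside the dense span")
  points
}

#' Write a snapshot series as a delimited table
#'
#' One tab-separated table with columns `time`, `cell`, then one integer
#' column per species; round-trips losslessly with [read_snapshots()].
#'
#' @param s a `snapshot_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(s, path) {
  blocks <- lapply(seq_along(s$times), function(i) {
    m <- s$counts[[i]]
    data.table::data.table(time = s$times[i], cell = seq_len(nrow(m)),
                           as.data.table_safe(m))
  })
  data.table::fwrite(data.table::rbindlist(blocks), path, sep = "\t")
  invisible(path)
}

as.data.table_safe <- function(m) {
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, colnames(m))
  dt
}

#' Read a snapshot series written by [write_snapshots()]
#' @param path file path.
#' @param noise_p capture efficiency the data were recorded at, if any.
#' @param replicate_id integer replicate label.
#' @return a `snapshot_series`.
#' @export
read_snapshots <- function(path, noise_p = NULL, replicate_id = 1L) {
  dt <- data.table::fread(path, sep = "\t")
  species <- setdiff(names(dt), c("time", "cell"))
  times <- sort(unique(dt$time))
  counts <- lapply(times, function(tt) {
    sub <- dt[dt$time == tt, ]
    sub <- sub[order(sub$cell), ]
    m <- as.matrix(sub[, species, with = FALSE])
    storage.mode(m) <- "integer"
    m
  })
  snapshot_series(times, counts, species, noise_p = noise_p,
                  replicate_id = replicate_id)
}
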