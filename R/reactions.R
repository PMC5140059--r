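#' Construct a reaction
#'
#' A reaction is a pair of multisets of species indices (reactants, products),
#' each of total multiplicity at most two, with an optional nonnegative
#' mass-action rate constant. Candidate reactions carry no rate.
#'
#' @param reactants integer vector of species indices (with repetition for
#'   multiplicity), length 0..2.
#' @param products integer vector of species indices, length 0..2.
#' @param rate nonnegative mass-action rate constant, or `NA` for a candidate.
#' @return an object of class `rn_reaction`.
#' @export
reaction <- function(reactants, products, rate = NA_real_) {
  reactants <- sort(as.integer(reactants))
  products <- sort(as.integer(products))
  if (length(reactants) > 2L || length(products) > 2L)
    stop("reactant and product multiplicities must total at most 2")
  if (identical(reactants, products))
    stop("reactant and product multisets must differ")
  if (!is.na(rate) && rate < 0)
    stop("rate constant must be nonnegative")
  structure(list(reactants = reactants, products = products,
                 rate = as.numeric(rate)),
            class = "rn_reaction")
}

#' Create a mass-action reaction network
#'
#' @param species character vector of unique species names; their order fixes
#'   the canonical species indexing 1..N.
#' @param reactions list of [reaction()] objects.
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(species, reactions = list()) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("species names must be unique")
  n <- length(species)
  for (r in reactions) {
    if (!inherits(r, "rn_reaction")) stop("reactions must be rn_reaction objects")
    idx <- c(r$reactants, r$products)
    if (length(idx) && (min(idx) < 1L || max(idx) > n))
      stop("reaction references species index outside 1..", n)
  }
  structure(list(species = species, reactions = reactions),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("reaction network: %d species, %d reactions\n",
              length(x$species), length(x$reactions)))
  for (i in seq_along(x$reactions))
    cat(sprintf("  [%d] %s   k = %s\n", i,
                format_reaction(x$reactions[[i]], x$species),
                format(x$reactions[[i]]$rate)))
  invisible(x)
}

#' Human-readable reaction formula
#' @param r an `rn_reaction`.
#' @param species character vector of species names.
#' @return a string like `"E + S -> ES"`.
#' @export
format_reaction <- function(r, species) {
  side <- function(idx) if (length(idx) == 0L) "0" else
    paste(species[idx], collapse = " + ")
  paste(side(r$reactants), "->", side(r$products))
}

#' Canonical identity key of a reaction (reactants and products as sorted
#' multisets); used for deduplication and ground-truth matching.
#' @param r an `rn_reaction`.
#' @return a string key.
#' @export
reaction_key <- function(r) {
  paste0(paste(r$reactants, collapse = "+"), ">",
         paste(r$products, collapse = "+"))
}

#' Stoichiometry vector of a reaction
#'
#' Entry i is the net change in species i: product multiplicity minus
#' reactant multiplicity.
#'
#' @param r an `rn_reaction`.
#' @param n_species number of species N.
#' @return integer vector of length `n_species` with entries in -2..2.
#' @export
stoichiometry_vector <- function(r, n_species) {
  idx <- c(r$reactants, r$products)
  if (length(idx) && max(idx) > n_species)
    stop("reaction references species index beyond n_species")
  s <- integer(n_species)
  for (i in r$reactants) s[i] <- s[i] - 1L
  for (i in r$products) s[i] <- s[i] + 1L
  s
}

#' Stochastic mass-action propensity of a reaction
#'
#' Returns the combinatorial factor g(x) such that the propensity is
#' `k * g(x)`: 1 for a source reaction, `x_a` for a unary reactant,
#' `x_a * x_b` for two distinct reactants, and `x_a * (x_a - 1)` for a
#' doubled reactant (the 1/2 symmetry factor is absorbed into k).
#'
#' @param r an `rn_reaction`.
#' @return a function mapping a count vector `x` to g(x).
#' @export
mass_action_propensity <- function(r) {
  re <- r$reactants
  if (length(re) == 0L) return(function(x) 1)
  if (length(re) == 1L) {
    a <- re[1]
    return(function(x) x[a])
  }
  a <- re[1]; b <- re[2]
  if (a == b) function(x) x[a] * (x[a] - 1) else function(x) x[a] * x[b]
}

#' Enumerate the unary/binary candidate reaction library
#'
#' Enumerates every candidate reaction of the three canonical forms over the
#' given species: conversions A -> B (one per unordered pair, canonical
#' direction lower index to higher index), splits A -> B + C with A, B, C
#' pairwise distinct, and associations A + B -> C with A, B, C pairwise
#' distinct. For N species this yields
#' C(N,2) + N*C(N-1,2) + C(N,2)*(N-2) candidates (2275 for N = 14).
#'
#' A module partition restricts enumeration to within-module candidates; a
#' limited explicit list of cross-module reactions may then be appended.
#'
#' @param species character vector of species names (length >= 2).
#' @param modules optional named list partitioning species names into
#'   modules; when given, only candidates whose species lie in one module
#'   are enumerated.
#' @param cross_reactions optional list of [reaction()] objects connecting
#'   modules, appended after the within-module candidates (duplicates of
#'   enumerated candidates are dropped).
#' @param known optional list of [reaction()] objects to flag as prior
#'   knowledge; each must be present in the final library.
#' @return an object of class `candidate_library`: a rate-free
#'   `reaction_network` plus a logical `known` mask.
#' @export
enumerate_candidates <- function(species, modules = NULL,
                                 cross_reactions = NULL, known = NULL) {
  species <- as.character(species)
  n <- length(species)
  if (n < 2L) stop("candidate enumeration requires at least 2 species")
  if (!is.null(modules)) {
    all_m <- unlist(modules, use.names = FALSE)
    if (!all(all_m %in% species))
      stop("module partition references unknown species")
    if (anyDuplicated(all_m))
      stop("module partition assigns a species to more than one module")
    groups <- lapply(modules, function(m) sort(match(m, species)))
  } else {
    groups <- list(seq_len(n))
  }

  conv <- list(); spl <- list(); assoc <- list()
  for (g in groups) {
    m <- length(g)
    if (m < 2L) next
    for (ii in 1:(m - 1L)) for (jj in (ii + 1L):m)
      conv[[length(conv) + 1L]] <- reaction(g[ii], g[jj])
    if (m >= 3L) {
      for (ai in seq_len(m)) {
        rest <- g[-ai]
        for (bi in 1:(m - 2L)) for (ci in (bi + 1L):(m - 1L))
          spl[[length(spl) + 1L]] <- reaction(g[ai], c(rest[bi], rest[ci]))
      }
      for (ai in 1:(m - 1L)) for (bi in (ai + 1L):m) {
        rest <- g[-c(ai, bi)]
        for (ci in seq_along(rest))
          assoc[[length(assoc) + 1L]] <- reaction(c(g[ai], g[bi]), rest[ci])
      }
    }
  }
  # deterministic canonical ordering: conversions, splits, associations,
  # each lexicographic by species indices
  ord_key <- function(lst) {
    m <- t(vapply(lst, function(r) {
      pad <- function(v) c(v, rep(0L, 2L - length(v)))
      c(pad(r$reactants), pad(r$products))
    }, integer(4)))
    do.call(order, as.data.frame(m))
  }
  reactions <- c(if (length(conv)) conv[ord_key(conv)],
                 if (length(spl)) spl[ord_key(spl)],
                 if (length(assoc)) assoc[ord_key(assoc)])
  keys <- vapply(reactions, reaction_key, character(1))
  if (!is.null(cross_reactions)) {
    for (r in cross_reactions) {
      k <- reaction_key(r)
      if (!(k %in% keys)) {
        reactions[[length(reactions) + 1L]] <- reaction(r$reactants, r$products)
        keys <- c(keys, k)
      }
    }
  }
  known_mask <- logical(length(reactions))
  if (!is.null(known)) {
    for (r in known) {
      i <- match(reaction_key(r), keys)
      if (is.na(i)) stop("known reaction not present in candidate library: ",
                         reaction_key(r))
      known_mask[i] <- TRUE
    }
  }
  structure(list(network = reaction_network(species, reactions),
                 known = known_mask),
            class = "candidate_library")
}

#' @export
print.candidate_library <- function(x, ...) {
  cat(sprintf("candidate library: %d species, %d candidate reactions (%d known)\n",
              length(x$network$species), length(x$network$reactions),
              sum(x$known)))
  invisible(x)
}

#' Built-in fixture networks
#'
#' `enzymatic` is the classical enzyme-substrate system with four species
#' (E, S, ES, P) and three reactions E + S -> ES, ES -> E + S, ES -> E + P.
#' `random_sparse` samples distinct candidates from the unconstrained
#' library, reproducibly under `seed`.
#'
#' @param kind `"enzymatic"` or `"random_sparse"`.
#' @param n_species number of species (random_sparse only).
#' @param n_reactions number of reactions to sample (random_sparse only).
#' @param seed integer seed (random_sparse only).
#' @param rates rate constants; for `enzymatic` a length-3 vector
#'   (binding, unbinding, catalysis), for `random_sparse` recycled over the
#'   sampled reactions.
#' @return a `reaction_network` with rates set.
#' @export
fixture_network <- function(kind = c("enzymatic", "random_sparse"),
                            n_species = 4L, n_reactions = 3L, seed = 1L,
                            rates = NULL) {
  kind <- match.arg(kind)
  if (kind == "enzymatic") {
    if (is.null(rates)) rates <- c(0.002, 0.1, 0.3)
    stopifnot(length(rates) == 3L)
    return(reaction_network(
      c("E", "S", "ES", "P"),
      list(reaction(c(1L, 2L), 3L, rates[1]),   # E + S -> ES
           reaction(3L, c(1L, 2L), rates[2]),   # ES -> E + S
           reaction(3L, c(1L, 4L), rates[3])))) # ES -> E + P
  }
  lib <- enumerate_candidates(paste0("X", seq_len(n_species)))
  L <- length(lib$network$reactions)
  if (n_reactions > L)
    stop("requested ", n_reactions, " reactions but library has only ", L)
  if (is.null(rates)) rates <- 0.1
  rates <- rep_len(rates, n_reactions)
  idx <- with_seed(seed, sample.int(L, n_reactions))
  rs <- lapply(seq_len(n_reactions), function(i) {
    r <- lib$network$reactions[[idx[i]]]
    reaction(r$reactants, r$products, rates[i])
  })
  reaction_network(lib$network$species, rs)
}

#' Read a reaction-network specification from a YAML file
#'
#' Expected blocks: `species` (list of names), `reactions` (list of maps with
#' `reactants`, `products` as species-name lists and optional `rate`),
#' optional `modules` (named map of species lists) and
#' `cross_module_reactions` (same shape as `reactions`, rate-free).
#'
#' @param path path to the YAML file.
#' @return a list with elements `network` (`reaction_network`), `modules`,
#'   `cross_module_reactions` (lists of `rn_reaction` or NULL).
#' @export
read_network_spec <- function(path) {
  sp <- yaml::read_yaml(path)
  if (is.null(sp$species)) stop("network spec is missing a 'species' block")
  species <- as.character(unlist(sp$species))
  parse_rxn <- function(x) {
    ridx <- match(as.character(unlist(x$reactants)), species)
    pidx <- match(as.character(unlist(x$products)), species)
    if (anyNA(ridx) || anyNA(pidx))
      stop("reaction references species not in the species block")
    reaction(ridx, pidx, if (is.null(x$rate)) NA_real_ else as.numeric(x$rate))
  }
  reactions <- lapply(sp$reactions, parse_rxn)
  cross <- if (!is.null(sp$cross_module_reactions))
    lapply(sp$cross_module_reactions, parse_rxn)
  list(network = reaction_network(species, reactions),
       modules = sp$modules, cross_module_reactions = cross)
}

#' Write a reaction network to a YAML specification file
#' @param network a `reaction_network`.
#' @param path output path.
#' @param modules optional named list of species-name modules.
#' @param cross_module_reactions optional list of `rn_reaction`.
#' @return `path`, invisibly.
#' @export
write_network_spec <- function(network, path, modules = NULL,
                               cross_module_reactions = NULL) {
  sp <- network$species
  as_block <- function(r) {
    b <- list(reactants = as.list(sp[r$reactants]),
              products = as.list(sp[r$products]))
    if (!is.na(r$rate)) b$rate <- r$rate
    b
  }
  out <- list(species = as.list(sp),
              reactions = lapply(network$reactions, as_block))
  if (!is.null(modules)) out$modules <- modules
  if (!is.null(cross_module_reactions))
    out$cross_module_reactions <- lapply(cross_module_reactions, as_block)
  yaml::write_yaml(out, path)
  invisible(path)
}
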