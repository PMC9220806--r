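#' Decoy ensembles and probabilistic models
#'
#' A probabilistic model quantifies how reproducible each link of a traced
#' backbone is. Many alternative paths ("decoys") are generated by re-seeding
#' pseudoatoms over a bracket of density thresholds and perturbing their
#' positions over a schedule of noise levels; every (threshold, noise) pair
#' yields one decoy. Decoy nodes are matched to a reference decoy by an
#' optimal bijective assignment, per-node average positions define the
#' average model, its path is re-solved, and each node receives the
#' percentage of decoys that reproduce its local connectivity (both chain
#' neighbors, direction-agnostic). The percentage is written to the PDB
#' B-factor column; the conventional display maps 100 percent to blue, 75 to
#' white, and 50 or below to red.
#'
#' @name prob_model
NULL

#' Generate a decoy path ensemble
#'
#' One decoy per (threshold, noise level) pair: pseudoatoms are seeded at the
#' threshold, perturbed at the noise level, and a path is solved. Decoy count
#' is exactly `length(thresholds) x length(noise_levels)`. With the default
#' probabilistic-run configuration -- a threshold bracket of (tau - sigma,
#' tau + sigma, sigma), i.e. three thresholds, and 20 noise levels evenly
#' spaced from 0 to 5 Angstrom -- this yields 60 decoys; a 5-threshold
#' bracket yields 100.
#'
#' @param grid a [density_grid].
#' @param threshold central working threshold (map units).
#' @param bracket optional `c(min, max, interval)` threshold specification;
#'   when `NULL`, defaults to `c(threshold - sigma, threshold + sigma, sigma)`
#'   with sigma the map standard deviation.
#' @param noise_levels Angstrom noise schedule; default
#'   `seq(0, 5, length.out = 20)`.
#' @param nres pseudoatoms per decoy.
#' @param method seeding method, see [seed_pseudoatoms()].
#' @param base_seed seed from which per-decoy seeds are derived.
#' @param time_cap TSP time cap per decoy, seconds.
#' @return A list of class `decoy_ensemble`: `decoys` (list of
#'   `list(pa, path, threshold, noise)`), `thresholds`, `noise_levels`,
#'   `reference_index`.
#' @export
generate_decoys <- function(grid, threshold, bracket = NULL,
                            noise_levels = default_noise_schedule(),
                            nres, method = "kmeans", base_seed = 0,
                            time_cap = default_tsp_time) {
  check_grid(grid)
  if (is.null(bracket)) bracket <- c(threshold - grid$sigma, threshold + grid$sigma, grid$sigma)
  if (length(bracket) != 3L || bracket[3] <= 0 || bracket[2] < bracket[1])
    stop("bracket must be c(min, max, interval) with interval > 0")
  thresholds <- seq(bracket[1], bracket[2], by = bracket[3])
  for (tau in thresholds) {
    n_above <- sum(grid$values > tau)
    if (n_above < nres)
      stop(sprintf("threshold %.4g leaves only %d voxels above it (need >= %d)",
                   tau, n_above, nres))
  }
  decoys <- vector("list", length(thresholds) * length(noise_levels))
  d <- 1L
  for (ti in seq_along(thresholds)) {
    tau <- thresholds[ti]
    seed_t <- as.integer(base_seed) + 1000L * ti
    pa0 <- seed_pseudoatoms(grid, tau, nres, method = method, seed = seed_t)
    for (ni in seq_along(noise_levels)) {
      pa <- perturb_positions(pa0, noise_levels[ni], seed = seed_t + ni)
      path <- solve_open(build_edge_matrix(pa), time_cap)
      decoys[[d]] <- list(pa = pa, path = path, threshold = tau,
                          noise = noise_levels[ni])
      d <- d + 1L
    }
  }
  ref <- reference_decoy_index(thresholds, noise_levels)
  structure(list(decoys = decoys, thresholds = thresholds,
                 noise_levels = noise_levels, reference_index = ref),
            class = "decoy_ensemble")
}

#' Default positional-noise schedule for probabilistic runs
#'
#' 20 evenly spaced values from 0 to 5 Angstrom.
#' @return Numeric vector of length 20.
#' @export
default_noise_schedule <- function() seq(0, 5, length.out = 20)

# the zero-noise decoy at the central threshold anchors correspondence
reference_decoy_index <- function(thresholds, noise_levels) {
  ti <- ceiling(length(thresholds) / 2)
  ni <- which.min(abs(noise_levels))
  (ti - 1L) * length(noise_levels) + ni
}

#' @export
print.decoy_ensemble <- function(x, ...) {
  cat(sprintf("decoy_ensemble: %d decoys (%d thresholds x %d noise levels)\n",
              length(x$decoys), length(x$thresholds), length(x$noise_levels)))
  invisible(x)
}

# optimal bijection (Hungarian assignment) minimizing total squared distance
match_nodes <- function(from_coords, to_coords) {
  cost <- cross_dist2(from_coords, to_coords)
  as.integer(clue::solve_LSAP(cost))
}

#' Average a decoy ensemble into a probabilistic model
#'
#' The reference decoy is the zero-noise decoy at the central threshold (or,
#' for hand-built ensembles, `e$reference_index`). Every other decoy's nodes
#' are matched to the reference by the bijection minimizing total squared
#' distance (all decoys live in the map's coordinate frame, so no alignment
#' beyond renumbering is needed). Average coordinates are per-matched-index
#' means, and the average model's path is solved with the same TSP contract
#' as any decoy.
#'
#' @param e a `decoy_ensemble`.
#' @param time_cap TSP time cap for the average path, seconds.
#' @return A list of class `probabilistic_model`: `avg_coords`, `avg_path`,
#'   `correspondence` (per-decoy reference-to-decoy index maps), and
#'   `probability = NULL` until [connectivity_probability()] fills it.
#' @export
correspond_and_average <- function(e, time_cap = default_tsp_time) {
  if (!inherits(e, "decoy_ensemble")) stop("e must be a decoy_ensemble")
  nd <- length(e$decoys)
  if (nd < 1) stop("empty ensemble")
  ref <- e$decoys[[e$reference_index]]$pa$coords
  n <- nrow(ref)
  corr <- vector("list", nd)
  acc <- matrix(0, n, 3)
  for (d in seq_len(nd)) {
    dc <- e$decoys[[d]]$pa$coords
    map_d <- if (d == e$reference_index) seq_len(n) else match_nodes(ref, dc)
    corr[[d]] <- map_d                      # ref index i  ->  decoy index map_d[i]
    acc <- acc + dc[map_d, , drop = FALSE]
  }
  avg <- acc / nd
  avg_path <- solve_open(build_edge_matrix(avg), time_cap)
  structure(list(avg_coords = avg, avg_path = avg_path,
                 correspondence = corr, reference_index = e$reference_index,
                 probability = NULL),
            class = "probabilistic_model")
}

# unordered neighbor sets for each node of an open path over n nodes
path_neighbors <- function(order, n) {
  nb <- vector("list", n)
  L <- length(order)
  for (p in seq_len(L)) {
    node <- order[p]
    nb[[node]] <- c(if (p > 1) order[p - 1], if (p < L) order[p + 1])
  }
  nb
}

#' Per-node connectivity probability
#'
#' For node `i` (in reference index space), let `A(i)` be its unordered
#' neighbor set in the average path (one neighbor at the termini, two
#' elsewhere) and `B_d(i)` the corresponding decoy node's neighbor set mapped
#' back to reference indices. The per-decoy score is the symmetric set
#' agreement `|A(i) \{intersection} B_d(i)| / max(|A(i)|, |B_d(i)|)`: paths
#' are direction-agnostic, so both chain neighbors count and one of two
#' matched scores 0.5; a terminus of the average path scores full marks only
#' in decoys that also make it a terminus with the same neighbor, so chains
#' whose ends wander across decoys are reported as unreliable there. The
#' probability is 100 times the mean score over decoys.
#'
#' @param model a `probabilistic_model` from [correspond_and_average()].
#' @param e the `decoy_ensemble` it was built from.
#' @return The model with `probability` (percent, per node in average-path
#'   residue order) filled in.
#' @export
connectivity_probability <- function(model, e) {
  if (!inherits(model, "probabilistic_model")) stop("model must be a probabilistic_model")
  n <- nrow(model$avg_coords)
  nd <- length(e$decoys)
  avg_nb <- path_neighbors(model$avg_path$order, n)
  score <- matrix(0, n, nd)
  for (d in seq_len(nd)) {
    map_d <- model$correspondence[[d]]       # ref i -> decoy node
    inv <- integer(n); inv[map_d] <- seq_len(n)  # decoy node -> ref i
    dec_nb <- path_neighbors(e$decoys[[d]]$path$order, n)
    for (i in seq_len(n)) {
      A <- avg_nb[[i]]
      B_ref <- inv[dec_nb[[map_d[i]]]]
      score[i, d] <- length(intersect(A, B_ref)) / max(length(A), length(B_ref))
    }
  }
  model$probability <- 100 * rowMeans(score)
  model
}

#' Write a probabilistic model as a Calpha PDB with B-factor probabilities
#'
#' Residues are numbered along the average path; the B-factor column carries
#' the connectivity probability in percent with two decimals.
#'
#' @param model a `probabilistic_model` with probabilities computed.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_probabilistic_pdb <- function(model, path) {
  if (is.null(model$probability)) stop("probabilities not computed; run connectivity_probability()")
  ord <- model$avg_path$order
  write_pdb(ca_atom_table(model$avg_coords[ord, , drop = FALSE],
                          bfactor = model$probability[ord]), path)
}

#' Dump a decoy ensemble as a multi-model PDB
#'
#' @param e a `decoy_ensemble`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(e, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (d in seq_along(e$decoys)) {
    writeLines(sprintf("MODEL %8d", d), con)
    dc <- e$decoys[[d]]
    tab <- ca_atom_table(dc$pa$coords[dc$path$order, , drop = FALSE])
    writeLines(sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
                       tab$serial, tab$resseq, tab$x, tab$y, tab$z, 1, 0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
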