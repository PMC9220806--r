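# Shared fixture builders and independent oracles. Fixtures are generated in
# code (no binary files); heavier systems are cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small helix-turn-helix system with simulated map
hth_system <- function(n = 30, seed = 1) {
  cached(sprintf("hth_%d_%d", n, seed),
         function() make_ground_truth(n, "helix-turn-helix", seed = seed))
}

# planted ligand/water/blob system for the residual pipeline
planted_system <- function(seed = 1) {
  cached(sprintf("planted_%d", seed), function() {
    sys <- make_ground_truth(30, "helix-turn-helix", noise_sigma = 0.02, seed = seed)
    plant_nonprotein(sys, "elongated", n_waters = 5, inconsistent_blob = TRUE,
                     seed = seed)
  })
}

# brute-force TSP oracle: exhaustive enumeration with node 1 fixed
brute_force_cycle_length <- function(w) {
  n <- nrow(w)
  stopifnot(n <= 9)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf
  for (p in perms(2:n)) {
    tour <- c(1L, p)
    nxt <- c(tour[-1], tour[1])
    l <- sum(w[cbind(tour, nxt)])
    if (l < best) best <- l
  }
  best
}

tour_len <- function(tour, w) {
  nxt <- c(tour[-1], tour[1])
  sum(w[cbind(tour, nxt)])
}

# fraction of true adjacent Calpha pairs that are adjacent (either direction)
# in a path over pseudoatoms, with truth-to-pseudoatom correspondence by
# optimal assignment
adjacency_recovery <- function(truth, coords, order) {
  mp <- as.integer(clue::solve_LSAP(
    outer(rowSums(truth^2), rowSums(coords^2), "+") - 2 * tcrossprod(truth, coords)))
  pos <- match(mp, order)
  sum(abs(diff(pos)) == 1) / (nrow(truth) - 1)
}

# run seeding + solve + refine on a fixture system, mirroring the pipeline's
# tracing stages (low-pass filter, seed on the filtered map, refine)
trace_fixture <- function(n, seed, motif = "helix-turn-helix") {
  ca <- make_ca_trace(n, motif, seed = seed)
  m0 <- simulate_map(ca, 4, 1)
  m <- lowpass_filter(m0, 4.5)
  thr <- 0.3 * max(m$values)
  pa <- seed_pseudoatoms(m, thr, n, "kmeans", seed = seed)
  p <- solve_open(build_edge_matrix(pa))
  r <- refine_path(p, pa, m, rounds = 3)
  list(truth = ca, coords = r$pa$coords, order = r$path$order,
       adjacency = adjacency_recovery(ca, r$pa$coords, r$path$order))
}
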