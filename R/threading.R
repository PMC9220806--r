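#' Sequence threading and all-atom conversion
#'
#' Threading assigns a 1-letter sequence to the residues of a backbone path.
#' Because a traced path has no intrinsic direction, both orientations can be
#' scored and the better one kept. The direction score is the Pearson
#' correlation between per-residue heavy-atom counts (a residue-size proxy)
#' and the local density mass -- the sum of map values over voxels within 3
#' Angstrom of each path node: big residues should sit in heavy density.
#' Ties (e.g. homopolymers or palindromic size profiles) resolve to forward.
#'
#' @name threading
NULL

# density mass within `radius` Angstrom of each point
local_density_mass <- function(grid, coords, radius = 3) {
  coords <- as_coords(coords)
  v <- grid$values
  d <- dim(v)
  out <- numeric(nrow(coords))
  r_vox <- ceiling(radius / grid$voxel_size)
  for (a in seq_len(nrow(coords))) {
    p <- coords[a, ]
    c_vox <- (p - grid$origin) / grid$voxel_size + 1
    lo <- pmax(floor(c_vox - r_vox), 1)
    hi <- pmin(ceiling(c_vox + r_vox), d)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (grid$origin[1] + (ii - 1) * grid$voxel_size[1] - p[1])^2
    dy2 <- (grid$origin[2] + (jj - 1) * grid$voxel_size[2] - p[2])^2
    dz2 <- (grid$origin[3] + (kk - 1) * grid$voxel_size[3] - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- v[ii, jj, kk, drop = FALSE]
    out[a] <- sum(sub[d2 <= radius^2])
  }
  out
}

#' Thread a sequence onto a backbone path
#'
#' @param path a `backbone_path` over `pa`.
#' @param pa the `pseudoatom_set` the path orders.
#' @param grid the working [density_grid].
#' @param sequence 1-letter amino-acid string; length must equal the path
#'   length.
#' @param try_reverse score both orientations and keep the better one;
#'   when `FALSE` the direction is fixed to forward.
#' @return A list of class `threaded_model`: `coords` (Calpha in path order,
#'   unchanged), `sequence` (as threaded, i.e. reversed if backward won),
#'   `direction`, `direction_scores` (named, both orientations), `atoms`
#'   (`NULL` until [build_all_atom()]).
#' @export
thread_sequence <- function(path, pa, grid, sequence, try_reverse = FALSE) {
  coords <- path_coords(path, pa)
  sequence <- gsub("\\s", "", sequence)
  n <- nrow(coords)
  if (nchar(sequence) != n)
    stop(sprintf("sequence length (%d) does not match path length (%d)",
                 nchar(sequence), n))
  bad <- setdiff(strsplit(sequence, "")[[1]], names(AA1))
  if (length(bad)) stop(sprintf("invalid residue code(s): %s", paste(unique(bad), collapse = ", ")))
  aa <- strsplit(sequence, "")[[1]]
  sizes <- AA_HEAVY[aa]
  mass <- local_density_mass(grid, coords)
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(0)
    stats::cor(a, b)
  }
  s_fwd <- safe_cor(sizes, mass)
  s_bwd <- if (try_reverse) safe_cor(rev(sizes), mass) else -Inf
  direction <- if (try_reverse && s_bwd > s_fwd) "backward" else "forward"
  seq_out <- if (direction == "backward") paste(rev(aa), collapse = "") else sequence
  structure(list(coords = coords, sequence = seq_out, direction = direction,
                 direction_scores = c(forward = s_fwd,
                                      backward = if (try_reverse) s_bwd else NA_real_),
                 atoms = NULL),
            class = "threaded_model")
}

unit <- function(v) { n <- sqrt(sum(v^2)); if (n < 1e-9) c(1, 0, 0) else v / n }

# a unit vector orthogonal to u, deterministic
perp_to <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(u, ref))
}

pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                 a[3] * b[1] - a[1] * b[3],
                                 a[1] * b[2] - a[2] * b[1])

#' Build a simple all-atom model from a threaded Calpha trace
#'
#' Places backbone N, C, O from consecutive Calpha triplets using ideal bond
#' lengths (N-Calpha 1.46, Calpha-C 1.53, C=O 1.23 Angstrom) and a
#' deterministic geometric construction, and a Cbeta (1.53 Angstrom,
#' tetrahedral) for non-glycine residues. No chemistry refinement is
#' attempted -- the output is a starting point for external real-space
#' refinement. Residues adjacent to a chain break (consecutive Calpha
#' distance above 4.5 Angstrom) get no bridging backbone atoms and are
#' reported in `gaps`.
#'
#' @param model a `threaded_model` from [thread_sequence()].
#' @return The model with `atoms` (a [read_pdb()]-shaped data.frame) and
#'   `gaps` (integer residue indices flagged at chain breaks) filled in.
#' @export
build_all_atom <- function(model) {
  if (!inherits(model, "threaded_model")) stop("model must be a threaded_model")
  ca <- model$coords
  n <- nrow(ca)
  aa <- strsplit(model$sequence, "")[[1]]
  seg_len <- sqrt(rowSums(diff(ca)^2))
  gap_after <- c(seg_len > 4.5, TRUE)        # gap_after[i]: no peptide i -> i+1
  gap_before <- c(TRUE, seg_len > 4.5)
  gaps <- sort(unique(c(which(seg_len > 4.5), which(seg_len > 4.5) + 1L)))

  rows <- list()
  serial <- 0L
  add <- function(name, res_i, xyz, elem) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      record = "ATOM", serial = serial, name = name, resname = AA1[[aa[res_i]]],
      chain = "A", resseq = res_i, x = xyz[1], y = xyz[2], z = xyz[3],
      occ = 1, bfactor = 0, element = elem, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    u_prev <- if (i > 1) unit(ca[i, ] - ca[i - 1, ]) else NULL
    u_next <- if (i < n) unit(ca[i + 1, ] - ca[i, ]) else NULL
    base_u <- u_next %||% u_prev
    nrm <- if (!is.null(u_prev) && !is.null(u_next)) {
      cr <- pracma_cross(u_prev, u_next)
      if (sqrt(sum(cr^2)) < 1e-6) perp_to(base_u) else unit(cr)
    } else perp_to(base_u)

    # N toward the previous residue, C toward the next, both tilted off-axis
    dir_n <- if (!is.null(u_prev)) unit(-0.80 * u_prev + 0.45 * nrm)
             else unit(-0.80 * base_u + 0.45 * nrm)
    dir_c <- if (!is.null(u_next)) unit(0.80 * u_next - 0.45 * nrm)
             else unit(0.80 * base_u - 0.45 * nrm)
    N <- ca[i, ] + 1.46 * dir_n
    C <- ca[i, ] + 1.53 * dir_c
    place_n <- !(gap_before[i] && i > 1)  # omit N if peptide to i-1 is broken
    place_c <- !(gap_after[i] && i < n)   # omit C/O if peptide to i+1 is broken
    if (i == 1) place_n <- TRUE
    if (i == n) place_c <- TRUE
    add("CA", i, ca[i, ], "C")
    if (place_n) add("N", i, N, "N")
    if (place_c) {
      add("C", i, C, "C")
      o_dir <- unit(pracma_cross(dir_c, nrm))
      add("O", i, C + 1.23 * o_dir, "O")
    }
    if (aa[i] != "G") {
      # tetrahedral Cbeta off the N-CA-C plane
      b1 <- unit(ca[i, ] - N); b2 <- unit(ca[i, ] - C)
      bis <- unit(b1 + b2)
      out_of_plane <- unit(pracma_cross(b2, b1))
      cb_dir <- unit(bis * sin(0.6046) + out_of_plane * cos(0.6046))
      add("CB", i, ca[i, ] + 1.53 * cb_dir, "C")
    }
  }
  model$atoms <- do.call(rbind, rows)
  model$gaps <- gaps
  model
}

#' Write a threaded (optionally all-atom) model to PDB
#'
#' Calpha-only when [build_all_atom()] has not been run.
#'
#' @param model a `threaded_model`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_threaded_pdb <- function(model, path) {
  if (!is.null(model$atoms)) return(write_pdb(model$atoms, path))
  aa <- strsplit(model$sequence, "")[[1]]
  tab <- ca_atom_table(model$coords)
  tab$resname <- unname(AA1[aa])
  write_pdb(tab, path)
}
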