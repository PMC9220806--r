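# Minimal fixed-column PDB coordinate I/O. Only ATOM/HETATM records are
# handled; columns follow the PDB v3.3 layout:
#   1-6 record, 7-11 serial, 13-16 atom name, 18-20 resName, 22 chainID,
#   23-26 resSeq, 31-38 x, 39-46 y, 47-54 z, 55-60 occupancy, 61-66 bfactor,
#   77-78 element.

#' Read ATOM/HETATM records from a PDB file
#'
#' @param path path to a PDB file.
#' @return A data.frame with columns `record`, `serial`, `name`, `resname`,
#'   `chain`, `resseq`, `x`, `y`, `z`, `occ`, `bfactor`, `element`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(lines) == 0L)
    return(data.frame(record = character(), serial = integer(), name = character(),
                      resname = character(), chain = character(), resseq = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      occ = numeric(), bfactor = numeric(), element = character(),
                      stringsAsFactors = FALSE))
  sub <- function(a, b) substr(lines, a, b)
  data.frame(
    record  = trimws(sub(1, 6)),
    serial  = as.integer(sub(7, 11)),
    name    = trimws(sub(13, 16)),
    resname = trimws(sub(18, 20)),
    chain   = trimws(sub(22, 22)),
    resseq  = as.integer(sub(23, 26)),
    x = as.numeric(sub(31, 38)),
    y = as.numeric(sub(39, 46)),
    z = as.numeric(sub(47, 54)),
    occ     = suppressWarnings(as.numeric(sub(55, 60))),
    bfactor = suppressWarnings(as.numeric(sub(61, 66))),
    element = trimws(sub(77, 78)),
    stringsAsFactors = FALSE
  )
}

#' Write ATOM/HETATM records to a PDB file
#'
#' @param atoms data.frame in the shape produced by [read_pdb()]; missing
#'   `occ`/`bfactor`/`element`/`chain` columns are filled with defaults.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(atoms, path) {
  n <- nrow(atoms)
  record  <- atoms$record  %||% rep("ATOM", n)
  serial  <- atoms$serial  %||% seq_len(n)
  name    <- atoms$name    %||% rep("CA", n)
  resname <- atoms$resname %||% rep("ALA", n)
  chain   <- atoms$chain   %||% rep("A", n)
  resseq  <- atoms$resseq  %||% seq_len(n)
  occ     <- atoms$occ     %||% rep(1, n)
  bfac    <- atoms$bfactor %||% rep(0, n)
  elem    <- atoms$element %||% substr(trimws(name), 1, 1)
  # atom-name column convention: 1-2 char element names start in column 14
  fmt_name <- ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
  lines <- sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   record, serial %% 100000L, fmt_name, resname, chain,
                   resseq %% 10000L, atoms$x, atoms$y, atoms$z, occ, bfac, elem)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

# Build a Calpha-only atom table from coordinates.
ca_atom_table <- function(coords, bfactor = 0, resname = "ALA", chain = "A") {
  coords <- as_coords(coords)
  n <- nrow(coords)
  data.frame(record = rep("ATOM", n), serial = seq_len(n),
             name = rep("CA", n), resname = rep_len(resname, n),
             chain = rep_len(chain, n), resseq = seq_len(n),
             x = coords[, 1], y = coords[, 2], z = coords[, 3],
             occ = rep(1, n), bfactor = rep_len(bfactor, n),
             element = rep("C", n), stringsAsFactors = FALSE)
}

AA1 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
         G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
         P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")

# Heavy (non-hydrogen) atom counts per residue type, used as a residue-size
# proxy when threading a sequence onto a path.
AA_HEAVY <- c(G=4, A=5, S=6, C=6, P=7, T=7, V=7, N=8, D=8, I=8, L=8, M=8,
              Q=9, E=9, K=9, H=10, R=11, F=11, Y=12, W=14)

#' Read a 1-letter protein sequence from a plain-text file
#'
#' Whitespace and FASTA-style header lines are ignored; letters are
#' upper-cased and validated against the 20 standard amino acids.
#'
#' @param path path to the sequence text file.
#' @return A single character string of 1-letter codes.
#' @export
read_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^>", lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(lines, collapse = "")))
  bad <- setdiff(strsplit(seq, "")[[1]], names(AA1))
  if (length(bad)) stop(sprintf("invalid residue code(s): %s", paste(unique(bad), collapse = ", ")))
  seq
}
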