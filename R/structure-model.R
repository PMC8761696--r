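#' Molecular structure model
#'
#' Atoms with 1-based residue numbering plus Cartesian coordinates in
#' Angstroms.  The atom table and the coordinate matrix are kept in
#' lock-step; residue numbers must be unique within a chain for a given
#' residue name ordering.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`,
#'   `resid`, `chain`, `element`.
#' @param xyz numeric n_atoms x 3 matrix, Angstroms.
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms),
            all(c("serial", "name", "resname", "resid", "chain", "element")
                %in% names(atoms)))
  xyz <- as.matrix(xyz)
  if (nrow(atoms) != nrow(xyz) || ncol(xyz) != 3)
    stop("xyz must be an n_atoms x 3 matrix", call. = FALSE)
  if (!all(is.finite(xyz))) stop("coordinates must be finite", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residue(s), chain(s) %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Trajectory of a structure model
#'
#' A topology plus per-frame coordinate sets (Angstroms) and frame times in
#' nanoseconds.
#'
#' @param topology a [structure_model()].
#' @param coords numeric array `n_atoms x 3 x n_frames`.
#' @param times frame times in ns, non-decreasing (default 0,1,2,...).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, coords,
                       times = seq_len(dim(coords)[3]) - 1) {
  stopifnot(inherits(topology, "structure_model"))
  coords <- as.array(coords)
  if (length(dim(coords)) != 3 || dim(coords)[1] != nrow(topology$atoms) ||
      dim(coords)[2] != 3)
    stop("coords must be n_atoms x 3 x n_frames matching the topology",
         call. = FALSE)
  if (length(times) != dim(coords)[3] || any(diff(times) < 0))
    stop("frame times must be non-decreasing, one per frame", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 times = as.numeric(times)), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms\n",
              dim(x$coords)[3], dim(x$coords)[1]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Select atoms of a structure model
#'
#' Either pass `chain` / `resid` / `names` filters directly, or a selection
#' string like `"chain A and resid 826-834 and name CA"`.  Residue ranges
#' `a-b` are 1-based and inclusive; multiple ranges or names may be comma-
#' or space-separated.  An empty result is an error.
#'
#' @param model a [structure_model()].
#' @param selection optional selection string.
#' @param chain chain id(s).
#' @param resid residue numbers, or a string of ranges like `"630-856"`.
#' @param names atom name(s), e.g. `"CA"`.
#' @return integer vector of atom indices.
#' @export
select_atoms <- function(model, selection = NULL, chain = NULL, resid = NULL,
                         names = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.null(selection)) {
    parsed <- parse_selection(selection)
    chain <- parsed$chain; resid <- parsed$resid; names <- parsed$names
  }
  if (is.character(resid)) resid <- parse_resid_ranges(resid)
  at <- model$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(names)) keep <- keep & at$name %in% names
  idx <- which(keep)
  if (length(idx) == 0) stop("selection resolves to no atoms", call. = FALSE)
  idx
}

parse_resid_ranges <- function(s) {
  parts <- strsplit(paste(s, collapse = ","), "[,[:space:]]+")[[1]]
  parts <- parts[nzchar(parts)]
  unlist(lapply(parts, function(p) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", p), " ")[[1]])
      seq(ab[1], ab[2])
    } else as.integer(p)
  }))
}

parse_selection <- function(s) {
  clauses <- strsplit(s, "\\s+and\\s+")[[1]]
  out <- list(chain = NULL, resid = NULL, names = NULL)
  for (cl in clauses) {
    toks <- strsplit(trimws(cl), "\\s+")[[1]]
    key <- toks[1]; vals <- toks[-1]
    if (key == "chain") out$chain <- vals
    else if (key == "resid") out$resid <- parse_resid_ranges(vals)
    else if (key == "name") out$names <- vals
    else stop(sprintf("unknown selection keyword: %s", key), call. = FALSE)
  }
  out
}

#' Read a PDB file
#'
#' Minimal fixed-column PDB parser covering ATOM/HETATM records and
#' MODEL/ENDMDL blocks.  A single-model file returns a
#' [structure_model()]; a multi-model file returns a [trajectory()] whose
#' topology is the first model.
#'
#' @param path PDB file path.
#' @param multi_model force trajectory output even for one model.
#' @return `structure_model` or `trajectory`.
#' @export
read_pdb <- function(path, multi_model = NA) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  model_id <- cumsum(model_starts)
  model_id[model_id == 0] <- 1L
  atom_lines <- lines[is_atom]
  if (length(atom_lines) == 0) stop("no ATOM records found", call. = FALSE)
  atom_model <- model_id[is_atom]
  parse_block <- function(ls) {
    data.frame(
      serial = as.integer(substr(ls, 7, 11)),
      name = trimws(substr(ls, 13, 16)),
      resname = trimws(substr(ls, 18, 20)),
      chain = trimws(substr(ls, 22, 22)),
      resid = as.integer(substr(ls, 23, 26)),
      x = as.numeric(substr(ls, 31, 38)),
      y = as.numeric(substr(ls, 39, 46)),
      z = as.numeric(substr(ls, 47, 54)),
      element = trimws(substr(ls, 77, 78)),
      stringsAsFactors = FALSE)
  }
  models <- unique(atom_model)
  first <- parse_block(atom_lines[atom_model == models[1]])
  atoms <- first[c("serial", "name", "resname", "resid", "chain", "element")]
  atoms$chain[atoms$chain == ""] <- "A"
  atoms$element[atoms$element == ""] <- substr(atoms$name, 1, 1)
  topo <- structure_model(atoms, unname(as.matrix(first[c("x", "y", "z")])))
  if (length(models) == 1 && !isTRUE(multi_model)) return(topo)
  coords <- array(NA_real_, c(nrow(atoms), 3, length(models)))
  coords[, , 1] <- topo$xyz
  for (k in seq_along(models)[-1]) {
    blk <- parse_block(atom_lines[atom_model == models[k]])
    if (nrow(blk) != nrow(atoms))
      stop("models differ in atom count", call. = FALSE)
    coords[, , k] <- unname(as.matrix(blk[c("x", "y", "z")]))
  }
  trajectory(topo, coords)
}

#' Write a structure or trajectory as PDB
#'
#' Writes standard fixed-column ATOM records; trajectories are written as
#' MODEL/ENDMDL blocks (multi-model PDB).
#'
#' @param x a [structure_model()] or [trajectory()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_block <- function(at, xyz) {
    name4 <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
                    sprintf(" %-3s", at$name))
    sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            at$serial %% 100000, name4, at$resname, at$chain, at$resid,
            xyz[, 1], xyz[, 2], xyz[, 3], at$element)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "structure_model")) {
    writeLines(fmt_block(x$atoms, x$xyz), con)
    writeLines("END", con)
  } else if (inherits(x, "trajectory")) {
    for (f in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL %8d", f), con)
      writeLines(fmt_block(x$topology$atoms, x$coords[, , f]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else stop("x must be a structure_model or trajectory", call. = FALSE)
  invisible(path)
}
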