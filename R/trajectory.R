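# Ensemble container and trajectory readers/writers.
# Units: coordinates in Angstrom, time in ps throughout the package.

#' Construct a coordinate ensemble
#'
#' An ensemble holds an F x N x 3 coordinate array (Angstrom) together with
#' the saving interval between frames (ps), the frame indices at which each
#' replicate starts (1-based), and a system label for provenance.
#'
#' @param coords numeric F x N x 3 array, all finite.
#' @param frame_interval frame saving interval in ps.
#' @param replicate_starts 1-based, strictly increasing frame indices where a
#'   new replicate begins; first element must be 1.
#' @param system_label free-text system name.
#' @return Object of class `ensemble`.
#' @export
ensemble <- function(coords, frame_interval = 100,
                     replicate_starts = 1L, system_label = "system") {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an F x N x 3 array", call. = FALSE)
  if (dim(coords)[1] < 1L) stop("ensemble needs at least one frame", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("all coordinates must be finite", call. = FALSE)
  rs <- as.integer(replicate_starts)
  if (length(rs) == 0L || rs[1] != 1L || is.unsorted(rs, strictly = TRUE) ||
      any(rs < 1L) || any(rs > dim(coords)[1]))
    stop("replicate_starts must be strictly increasing, start at 1 and lie within [1, F]",
         call. = FALSE)
  structure(list(coords = coords,
                 frame_interval = as.numeric(frame_interval),
                 replicate_starts = rs,
                 system_label = as.character(system_label)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Ensemble '%s': %d frames x %d atoms (%g ps/frame, %d replicate(s))\n",
              x$system_label, n_frames(x), n_atoms(x), x$frame_interval,
              length(x$replicate_starts)))
  invisible(x)
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_frames <- function(x) dim(x$coords)[1]

#' @rdname ensemble
#' @export
n_atoms <- function(x) dim(x$coords)[2]

#' Extract one frame as an N x 3 matrix
#' @param x an `ensemble`.
#' @param i frame index.
#' @export
frame_coords <- function(x, i) {
  m <- x$coords[i, , , drop = FALSE]
  dim(m) <- dim(x$coords)[2:3]
  m
}

#' Concatenate replicate ensembles with provenance
#'
#' Stacks the frames of several ensembles (the analysis convention for
#' replicate simulations of one system) and records where each source starts
#' in `replicate_starts`.
#'
#' @param ensembles list of `ensemble` objects sharing atom count and frame
#'   interval.
#' @param system_label label for the result; default taken from the first.
#' @return A single `ensemble`.
#' @export
concatenate_ensembles <- function(ensembles, system_label = NULL) {
  stopifnot(is.list(ensembles), length(ensembles) >= 1L)
  lapply(ensembles, function(e) stopifnot(inherits(e, "ensemble")))
  if (length(ensembles) == 1L) return(ensembles[[1]])
  na <- vapply(ensembles, n_atoms, integer(1))
  if (length(unique(na)) != 1L)
    stop("shape error: ensembles have different atom counts (",
         paste(unique(na), collapse = ", "), ")", call. = FALSE)
  fi <- vapply(ensembles, function(e) e$frame_interval, numeric(1))
  if (length(unique(fi)) != 1L)
    stop("ensembles have different frame intervals", call. = FALSE)
  nf <- vapply(ensembles, n_frames, integer(1))
  coords <- array(0, dim = c(sum(nf), na[1], 3))
  off <- 0L
  for (e in ensembles) {
    coords[off + seq_len(n_frames(e)), , ] <- e$coords
    off <- off + n_frames(e)
  }
  ensemble(coords, fi[1],
           replicate_starts = cumsum(c(1L, nf[-length(nf)])),
           system_label = system_label %||% ensembles[[1]]$system_label)
}

#' Split a concatenated ensemble back into its replicates
#' @param x an `ensemble`.
#' @return list of `ensemble` objects, one per replicate block.
#' @export
split_replicates <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  starts <- x$replicate_starts
  ends <- c(starts[-1] - 1L, n_frames(x))
  lapply(seq_along(starts), function(i) {
    ensemble(x$coords[starts[i]:ends[i], , , drop = FALSE], x$frame_interval,
             system_label = x$system_label)
  })
}

# ---- readers -----------------------------------------------------------

#' Read a coordinate trajectory
#'
#' Supported formats: multi-model PDB (parsed natively), DCD (via
#' `bio3d::read.dcd`) and XTC (read through the system's Python `mdtraj`
#' library, which converts to DCD in a temporary directory). Coordinates are
#' returned in Angstrom; frame order is preserved.
#'
#' @param path trajectory file.
#' @param topology the matching [topology()] (atom count is validated).
#' @param format `"pdb"`, `"dcd"` or `"xtc"`; default guessed from the file
#'   extension.
#' @param frame_interval saving interval in ps (metadata; default 100).
#' @param system_label label stored on the ensemble.
#' @return An [ensemble()].
#' @export
read_trajectory <- function(path, topology,
                            format = c("auto", "pdb", "dcd", "xtc"),
                            frame_interval = 100, system_label = NULL) {
  stopifnot(inherits(topology, "topology"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "dcd", "xtc")) ext
              else stop("unsupported format: cannot infer trajectory format from '",
                        path, "'", call. = FALSE)
  }
  coords <- switch(format,
    pdb = .read_multimodel_pdb(path),
    dcd = .read_dcd_frames(path),
    xtc = .read_xtc_frames(path, topology),
    stop("unsupported format '", format, "'", call. = FALSE))
  if (dim(coords)[2] != nrow(topology))
    stop(sprintf("shape error: trajectory has %d atoms but topology has %d",
                 dim(coords)[2], nrow(topology)), call. = FALSE)
  ensemble(coords, frame_interval = frame_interval,
           system_label = system_label %||% basename(path))
}

.read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("empty input: no ATOM/HETATM records in '", path, "'", call. = FALSE)
  model_id <- cumsum(grepl("^MODEL", lines))
  if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
  model_id[!is_atom] <- NA_integer_
  at <- lines[is_atom]
  short <- nchar(at) < 54
  if (any(short))
    stop(sprintf("format error: truncated ATOM/HETATM record at line %d of '%s'",
                 which(is_atom)[which(short)[1]], path), call. = FALSE)
  xyz <- cbind(as.numeric(substr(at, 31, 38)),
               as.numeric(substr(at, 39, 46)),
               as.numeric(substr(at, 47, 54)))
  if (any(!is.finite(xyz)))
    stop("format error: unparseable coordinates in '", path, "'", call. = FALSE)
  mid <- model_id[is_atom]
  mid[mid == 0L] <- 1L
  counts <- table(mid)
  if (length(unique(as.integer(counts))) != 1L)
    stop("shape error: models in '", path, "' have different atom counts",
         call. = FALSE)
  n <- as.integer(counts[1])
  f <- length(counts)
  coords <- array(0, dim = c(f, n, 3))
  ord <- order(as.integer(mid))
  xyz <- xyz[ord, , drop = FALSE]
  for (k in seq_len(f))
    coords[k, , ] <- xyz[(k - 1L) * n + seq_len(n), ]
  coords
}

.read_dcd_frames <- function(path) {
  xyz <- suppressWarnings(bio3d::read.dcd(path, verbose = FALSE))
  xyz <- unclass(xyz)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  f <- nrow(xyz); n <- ncol(xyz) / 3L
  coords <- array(0, dim = c(f, n, 3))
  coords[, , 1] <- xyz[, seq(1, 3 * n, 3)]
  coords[, , 2] <- xyz[, seq(2, 3 * n, 3)]
  coords[, , 3] <- xyz[, seq(3, 3 * n, 3)]
  coords
}

.read_xtc_frames <- function(path, topology) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("unsupported format: reading XTC requires a python interpreter with mdtraj on the PATH",
         call. = FALSE)
  tmp <- tempfile("xtcbridge")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  top_pdb <- file.path(tmp, "top.pdb")
  coords0 <- topology_coords(topology)
  if (is.null(coords0)) coords0 <- matrix(0, nrow(topology), 3)
  write_pdb_topology(topology, coords0, top_pdb)
  out_dcd <- file.path(tmp, "traj.dcd")
  script <- file.path(tmp, "convert.py")
  writeLines(c(
    "import sys, mdtraj",
    "t = mdtraj.load(sys.argv[1], top=sys.argv[2])",
    "t.save_dcd(sys.argv[3])"), script)
  status <- system2(py, c(script, shQuote(path), shQuote(top_pdb),
                          shQuote(out_dcd)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_dcd))
    stop("XTC read failed via mdtraj bridge:\n",
         paste(status, collapse = "\n"), call. = FALSE)
  .read_dcd_frames(out_dcd)
}

# ---- writers -----------------------------------------------------------

#' Write a trajectory
#'
#' Multi-model PDB is written natively; DCD is written in the CHARMM binary
#' layout readable by standard trajectory tools.
#'
#' @param x an [ensemble()].
#' @param topology the matching [topology()].
#' @param path output file.
#' @param format `"pdb"` or `"dcd"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, topology, path,
                             format = c("auto", "pdb", "dcd")) {
  stopifnot(inherits(x, "ensemble"), inherits(topology, "topology"),
            n_atoms(x) == nrow(topology))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("pdb", "dcd")) ext
              else stop("unsupported format for writing: '", ext, "'",
                        call. = FALSE)
  }
  switch(format,
         pdb = .write_multimodel_pdb(x, topology, path),
         dcd = .write_dcd(x, path))
  invisible(path)
}

.write_multimodel_pdb <- function(x, top, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(x))) {
    writeLines(sprintf("MODEL %8d", k), con)
    writeLines(.pdb_atom_lines(top, frame_coords(x, k)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_dcd <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  f <- n_frames(x); n <- n_atoms(x)
  wrec <- function(write_payload, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4)
    write_payload()
    writeBin(as.integer(nbytes), con, size = 4)
  }
  # header: 'CORD' + 20 int32 control words (word 10 is the float timestep)
  wrec(function() {
    writeChar("CORD", con, nchars = 4, eos = NULL)
    icntrl <- integer(20)
    icntrl[1] <- f          # number of frames
    icntrl[2] <- 1L         # first step
    icntrl[3] <- 1L         # step interval
    icntrl[4] <- f
    icntrl[20] <- 24L       # CHARMM version stamp
    writeBin(icntrl[1:9], con, size = 4)
    writeBin(1.0, con, size = 4)   # AKMA timestep placeholder
    writeBin(icntrl[11:20], con, size = 4)
  }, 84)
  title <- sprintf("%-80s", "ensemble written by conflock")
  wrec(function() {
    writeBin(1L, con, size = 4)
    writeChar(title, con, nchars = 80, eos = NULL)
  }, 84)
  wrec(function() writeBin(as.integer(n), con, size = 4), 4)
  for (k in seq_len(f)) {
    fr <- frame_coords(x, k)
    for (d in 1:3)
      wrec(function() writeBin(as.numeric(fr[, d]), con, size = 4), 4 * n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
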