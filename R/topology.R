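# Topology: atoms, residues and chemical role flags.

.WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "SPC")

.ELEMENT_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  "NA" = 22.990, CL = 35.45, K = 39.098, CA = 40.078
)

#' Construct a topology from per-atom fields
#'
#' A topology is a data frame with one row per atom carrying the atom's
#' identity (`index`, `name`, `element`, `resno`, `resname`, `chain`, `mass`,
#' `hetatm`) and logical chemical role flags used by selections and contact
#' detection: `calpha`, `backbone`, `ligand`, `water`, `apolar`, `donor`,
#' `acceptor`, `pos_charged`, `neg_charged`.
#'
#' Role flags follow a documented name-based rule table (the package performs
#' no bond perception beyond it); see [read_topology()] for the rules.
#'
#' @param atoms data.frame with at least `name`, `element`, `resno`,
#'   `resname`; missing identity columns are filled with defaults and role
#'   flags are inferred with [infer_roles()].
#' @return An object of class `topology` (a data.frame).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  if (nrow(atoms) == 0L)
    stop("empty topology: zero atoms", call. = FALSE)
  if (is.null(atoms$index)) atoms$index <- seq_len(nrow(atoms))
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$hetatm)) atoms$hetatm <- FALSE
  if (is.null(atoms$element))
    atoms$element <- .guess_element(atoms$name)
  if (is.null(atoms$mass)) atoms$mass <- .element_mass(atoms$element)
  if (anyDuplicated(atoms$index) || !identical(as.integer(atoms$index),
                                               seq_len(nrow(atoms))))
    stop("atom indices must be unique and contiguous from 1", call. = FALSE)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("every atom must have a positive mass", call. = FALSE)
  flags <- infer_roles(atoms)
  for (nm in names(flags)) atoms[[nm]] <- flags[[nm]]
  class(atoms) <- c("topology", "data.frame")
  atoms
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s)\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              length(unique(x$chain))))
  cat(sprintf("  Calpha: %d  ligand: %d  water: %d\n",
              sum(x$calpha), sum(x$ligand), sum(x$water)))
  invisible(x)
}

.guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  ifelse(two %in% c("SE", "FE", "ZN", "MG", "CL"), two, el)
}

.element_mass <- function(element) {
  m <- .ELEMENT_MASSES[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Infer chemical role flags from atom and residue names
#'
#' Rule table (name-based, no bond perception):
#' \itemize{
#'   \item water: residue name in HOH/WAT/TIP3/TIP/SOL/SPC.
#'   \item ligand: HETATM record and not water.
#'   \item calpha: atom named `CA` with element C, excluding ligand and water.
#'   \item backbone: protein atoms named N, CA, C, O or OXT.
#'   \item apolar (hydrophobic-contact candidate): element C except the
#'     backbone carbonyl carbon `C`.
#'   \item donor heavy atom: any protein/ligand nitrogen; oxygens with
#'     hydroxyl-type names (OG, OG1, OH, OW); water oxygen; ligand oxygens.
#'   \item acceptor heavy atom: any oxygen; histidine ring nitrogens
#'     (ND1, NE2); ligand nitrogens.
#'   \item pos_charged: LYS NZ, ARG NE/NH1/NH2; a free amino-acid ligand's
#'     amine nitrogen `N`.
#'   \item neg_charged: GLU OE1/OE2, ASP OD1/OD2; ligand carboxylate
#'     oxygens (O, OXT).
#' }
#'
#' @param atoms data.frame with `name`, `element`, `resname`, `hetatm`.
#' @return list of logical vectors, one per role flag.
#' @export
infer_roles <- function(atoms) {
  nm  <- toupper(trimws(atoms$name))
  el  <- toupper(atoms$element)
  res <- toupper(trimws(atoms$resname))
  het <- as.logical(atoms$hetatm)

  water  <- res %in% .WATER_RESNAMES
  ligand <- het & !water
  prot   <- !ligand & !water
  calpha   <- prot & nm == "CA" & el == "C"
  backbone <- prot & nm %in% c("N", "CA", "C", "O", "OXT")
  apolar <- el == "C" & nm != "C"
  donor <- (el == "N" & !water) |
    (el == "O" & nm %in% c("OG", "OG1", "OH", "OW")) |
    (el == "O" & water) |
    (el == "O" & ligand)
  acceptor <- el == "O" |
    (el == "N" & nm %in% c("ND1", "NE2") & res == "HIS") |
    (el == "N" & ligand)
  pos_charged <- (res == "LYS" & nm == "NZ") |
    (res == "ARG" & nm %in% c("NE", "NH1", "NH2")) |
    (ligand & el == "N" & nm == "N")
  neg_charged <- (res == "GLU" & nm %in% c("OE1", "OE2")) |
    (res == "ASP" & nm %in% c("OD1", "OD2")) |
    (ligand & el == "O" & nm %in% c("O", "OXT"))

  list(calpha = calpha, backbone = backbone, ligand = ligand, water = water,
       apolar = apolar, donor = donor, acceptor = acceptor,
       pos_charged = pos_charged, neg_charged = neg_charged)
}

#' Read a PDB topology
#'
#' Parses ATOM/HETATM records of a PDB file into a [topology()]. Residue
#' numbers are taken verbatim (1-based, no renumbering), so published residue
#' labels such as Cys125 or Glu451 are addressable by number. Role flags are
#' derived from atom/residue names via the rule table in [infer_roles()].
#'
#' @param path path to a PDB file.
#' @return A `topology`.
#' @export
read_topology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0L)
    stop("empty input: no ATOM/HETATM records in '", path, "'", call. = FALSE)
  at <- lines[keep]
  short <- nchar(at) < 54
  if (any(short))
    stop(sprintf("format error: truncated ATOM/HETATM record at line %d of '%s'",
                 keep[which(short)[1]], path), call. = FALSE)
  x <- suppressWarnings(as.numeric(substr(at, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(at, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(at, 47, 54)))
  resno <- suppressWarnings(as.integer(substr(at, 23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno))
  if (length(bad))
    stop(sprintf("format error: unparseable coordinate fields at line %d of '%s'",
                 keep[bad[1]], path), call. = FALSE)
  name <- trimws(substr(at, 13, 16))
  element <- trimws(substr(at, 77, 78))
  element[element == ""] <- .guess_element(name[element == ""])
  atoms <- data.frame(
    index = seq_along(at), name = name, element = toupper(element),
    resno = resno, resname = trimws(substr(at, 18, 20)),
    chain = substr(at, 22, 22), hetatm = substr(at, 1, 6) == "HETATM",
    stringsAsFactors = FALSE)
  # multi-model files repeat the atom block; keep the first model
  n_unique <- nrow(atoms)
  first_model <- grepl("^MODEL", lines)
  if (sum(first_model) > 1) {
    model_starts <- which(first_model)
    second <- keep >= model_starts[2]
    if (any(!second)) n_unique <- sum(!second)
    atoms <- atoms[seq_len(n_unique), , drop = FALSE]
    atoms$index <- seq_len(n_unique)
  }
  top <- topology(atoms)
  attr(top, "coords") <- cbind(x, y, z)[seq_len(nrow(top)), , drop = FALSE]
  attr(top, "source") <- path
  top
}

#' First-model coordinates stored with a topology read from PDB
#' @param topology a `topology` from [read_topology()].
#' @return N x 3 coordinate matrix in Angstrom, or NULL.
#' @export
topology_coords <- function(topology) attr(topology, "coords")

#' Write a topology (plus coordinates) as a PDB file
#'
#' @param topology a `topology`.
#' @param coords N x 3 matrix in Angstrom; defaults to the coordinates stored
#'   on the topology.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_topology <- function(topology, coords = topology_coords(topology),
                               path) {
  stopifnot(!is.null(coords), nrow(coords) == nrow(topology))
  writeLines(c(.pdb_atom_lines(topology, coords), "END"), path)
  invisible(path)
}

.pdb_atom_lines <- function(top, xyz) {
  rec <- ifelse(top$hetatm, "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(top$name) < 4, sprintf(" %-3s", top$name),
                  substr(top$name, 1, 4))
  sprintf("%s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, top$index %% 100000L, name4, substr(top$resname, 1, 3),
          top$chain, top$resno %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(top$element, 1, 2))
}
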