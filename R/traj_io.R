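#' @importFrom utils read.csv write.csv head tail
#' @importFrom stats sd setNames
NULL

.AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "HSD", "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO",
             "SER", "THR", "TRP", "TYR", "VAL")

#' Derive an element symbol from an atom name
#'
#' PDB/GRO atom names encode the element in their leading letters
#' (`"SG"` -> S, `"C16"` -> C, `"OG"` -> O). Digits and primes are stripped
#' and the first letter is taken, except for recognised two-letter symbols.
#'
#' @param name character vector of atom names.
#' @return character vector of element symbols.
#' @export
guess_element <- function(name) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE")
  vapply(name, function(nm) {
    s <- gsub("[0-9'\"]", "", toupper(nm))
    if (nchar(s) == 0L) stop("cannot derive element from atom name '", nm, "'")
    if (substr(s, 1, 2) %in% two) substr(s, 1, 2) else substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' Atomic mass from element symbol
#'
#' Standard atomic weights (amu) via the bio3d mass table.
#'
#' @param element character vector of element symbols.
#' @return numeric masses in amu.
#' @export
element_mass <- function(element) {
  tab <- .element_table()
  tab <- tab[is.finite(tab$mass) & tab$mass > 0, ]
  m <- tab$mass[match(toupper(element), toupper(as.character(tab$symb)))]
  if (any(!is.finite(m)))
    stop("no mass table entry for element(s): ",
         paste(unique(element[!is.finite(m)]), collapse = ", "))
  m
}

.element_env <- new.env(parent = emptyenv())
.element_table <- function() {
  if (is.null(.element_env$tab)) {
    e <- new.env()
    utils::data("elements", package = "bio3d", envir = e)
    .element_env$tab <- e$elements
  }
  .element_env$tab
}

#' Construct a topology table
#'
#' A topology is an ordered data frame of atom records carrying author residue
#' numbering, so that catalytic residues are addressable by their literature
#' names (e.g. residue 156 of hDHHC20).
#'
#' @param name atom names.
#' @param resname 3-letter residue names.
#' @param resid author residue numbers (integer).
#' @param chain chain identifiers.
#' @param element element symbols; derived from `name` when `NULL`.
#' @param serial atom serial numbers; `1:n` when `NULL`.
#' @param mass atomic masses in amu; from `element` when `NULL`.
#' @return data.frame of class `"topology"` with columns
#'   `serial, name, element, resname, resid, chain, mass`.
#' @export
topology <- function(name, resname, resid, chain = "A",
                     element = NULL, serial = NULL, mass = NULL) {
  n <- length(name)
  if (is.null(serial)) serial <- seq_len(n)
  if (is.null(element)) element <- guess_element(name)
  if (is.null(mass)) mass <- element_mass(element)
  stopifnot(all(mass > 0))
  top <- data.frame(serial = as.integer(serial), name = as.character(name),
                    element = toupper(as.character(element)),
                    resname = as.character(resname),
                    resid = as.integer(resid),
                    chain = rep_len(as.character(chain), n),
                    mass = as.numeric(mass),
                    stringsAsFactors = FALSE)
  key <- paste(top$chain, top$resid, top$name)
  if (anyDuplicated(key))
    stop("duplicate (chain, resid, name) atom records: ",
         paste(head(key[duplicated(key)], 3), collapse = "; "))
  class(top) <- c("topology", "data.frame")
  top
}

#' Construct a trajectory
#'
#' Ordered coordinate frames over a shared topology. Coordinates are in
#' Angstrom; frame times in picoseconds and strictly increasing.
#'
#' @param topology a [topology()] table.
#' @param xyz numeric array `c(n_atoms, 3, n_frames)` (a single `n x 3`
#'   matrix is promoted to one frame).
#' @param box optional orthorhombic box lengths in Angstrom: length-3 vector
#'   (constant) or `n_frames x 3` matrix.
#' @param time frame times in ps; defaults to `(0:(nf-1)) * stride`.
#' @param stride analysis timestep in ps used when `time` is absent.
#' @return object of class `"traj"`.
#' @export
trajectory <- function(topology, xyz, box = NULL, time = NULL, stride = 100) {
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(nrow(xyz), 3L, 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (dim(xyz)[3] < 1L) stop("trajectory must contain at least one frame")
  if (dim(xyz)[1] != nrow(topology))
    stop("coordinate count (", dim(xyz)[1], ") != topology atom count (",
         nrow(topology), ")")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in trajectory")
  nf <- dim(xyz)[3]
  if (is.null(time)) time <- (seq_len(nf) - 1) * stride
  if (nf > 1L && any(diff(time) <= 0))
    stop("frame times must be strictly increasing")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
    stopifnot(nrow(box) == nf, ncol(box) == 3)
  }
  structure(list(topology = topology, xyz = xyz, box = box,
                 time = as.numeric(time)),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat("MD trajectory:", dim(x$xyz)[1], "atoms,", dim(x$xyz)[3], "frames",
      if (!is.null(x$box)) "(box set)" else "(no box)", "\n")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a trajectory.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Extract one frame's coordinates
#' @param traj a trajectory.
#' @param i frame index.
#' @return `n_atoms x 3` coordinate matrix (Angstrom).
#' @export
frame_xyz <- function(traj, i = 1L) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range: ", i)
  traj$xyz[, , i, drop = TRUE]
}

.parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  v <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                    substr(cl[1], 25, 33)))
  if (any(!is.finite(v)) || all(v == 1)) return(NULL)  # placeholder box
  v
}

.topology_from_pdb <- function(pdb) {
  a <- pdb$atom
  ele <- a$elesy
  bad <- is.na(ele) | !nzchar(trimws(ele))
  if (any(bad)) ele[bad] <- guess_element(a$elety[bad])
  topology(name = a$elety, resname = a$resid, resid = a$resno,
           chain = ifelse(is.na(a$chain), "A", a$chain),
           element = trimws(ele), serial = a$eleno)
}

.read_gro_block <- function(lines, start) {
  natoms <- as.integer(trimws(lines[start + 1L]))
  if (is.na(natoms))
    stop("GRO parse error at line ", start + 1L, ": bad atom count")
  rows <- lines[(start + 2L):(start + 1L + natoms)]
  resid <- as.integer(substr(rows, 1, 5))
  resname <- trimws(substr(rows, 6, 10))
  name <- trimws(substr(rows, 11, 15))
  # coordinate field width from the dot spacing of the first atom line
  # (standard GRO is %8.3f; higher-precision files use wider fields)
  dots <- gregexpr(".", substr(rows[1], 21, nchar(rows[1])),
                   fixed = TRUE)[[1]]
  w <- if (length(dots) >= 2) dots[2] - dots[1] else 8L
  x <- suppressWarnings(as.numeric(substr(rows, 21, 20 + w)))
  y <- suppressWarnings(as.numeric(substr(rows, 21 + w, 20 + 2 * w)))
  z <- suppressWarnings(as.numeric(substr(rows, 21 + 2 * w, 20 + 3 * w)))
  if (any(is.na(c(x, y, z))))
    stop("GRO parse error near line ",
         start + 1L + which(is.na(x) | is.na(y) | is.na(z))[1],
         ": malformed coordinate field")
  boxline <- as.numeric(strsplit(trimws(lines[start + 2L + natoms]),
                                 "[[:space:]]+")[[1]])
  list(natoms = natoms, resid = resid, resname = resname, name = name,
       xyz = cbind(x, y, z) * 10,            # nm -> Angstrom
       box = if (length(boxline) >= 3) boxline[1:3] * 10 else NULL,
       next_start = start + 3L + natoms)
}

#' Read a molecular structure file
#'
#' Reads a PDB (first MODEL of a multi-model file) or GRO file into a
#' topology plus a one-frame trajectory. GRO coordinates (nm) are converted
#' to Angstrom on read; author residue numbering is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"pdb"` or `"gro"`.
#' @return a one-frame [trajectory()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "pdb") {
    t <- read_trajectory(path)
    return(trajectory(t$topology, t$xyz[, , 1, drop = FALSE],
                      box = if (!is.null(t$box)) t$box[1, ],
                      time = t$time[1]))
  }
  lines <- readLines(path)
  b <- .read_gro_block(lines, 1L)
  top <- topology(name = b$name, resname = b$resname, resid = b$resid,
                  chain = "A")
  trajectory(top, b$xyz, box = b$box, time = 0)
}

#' Read a trajectory
#'
#' Multi-model PDB (the canonical text dialect here), a GRO frame series, or
#' a binary DCD stream with a separate topology. Frames are ordered by time
#' with identical atom order throughout.
#'
#' @param path coordinate file path.
#' @param topology required for DCD; optional atom-count check otherwise.
#' @param stride frame spacing in ps used to synthesise times (default 100).
#' @return a [trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, stride = 100) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    if (is.null(topology)) stop("DCD input requires a topology")
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    arr <- .xyzmat_to_array(xyz, nrow(topology), path)
    return(trajectory(topology, arr, stride = stride))
  }
  if (ext == "xtc")
    stop("XTC input is not supported; convert to multi-model PDB, GRO or DCD")
  if (ext == "gro") {
    lines <- readLines(path)
    start <- 1L; frames <- list(); box <- list(); top <- NULL
    while (start + 1L <= length(lines) && nzchar(trimws(lines[start + 1L]))) {
      b <- .read_gro_block(lines, start)
      if (is.null(top)) {
        top <- topology(name = b$name, resname = b$resname, resid = b$resid,
                        chain = "A")
      } else if (b$natoms != nrow(top)) {
        stop("frame ", length(frames) + 1L, ": atom count ", b$natoms,
             " != ", nrow(top))
      }
      frames[[length(frames) + 1L]] <- b$xyz
      box[[length(box) + 1L]] <- if (is.null(b$box)) rep(NA_real_, 3) else b$box
      start <- b$next_start
      if (start > length(lines)) break
    }
    arr <- array(unlist(frames), dim = c(nrow(top), 3, length(frames)))
    boxm <- do.call(rbind, box)
    if (all(is.na(boxm))) boxm <- NULL
    if (!is.null(topology)) top <- topology
    return(trajectory(top, arr, box = boxm, stride = stride))
  }
  # multi-model (or single-model) PDB
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  top <- if (is.null(topology)) .topology_from_pdb(pdb) else topology
  nf <- nrow(pdb$xyz)
  if (ncol(pdb$xyz) != 3L * nrow(top))
    stop("frame atom count (", ncol(pdb$xyz) / 3,
         ") != topology atom count (", nrow(top), ")")
  arr <- .xyzmat_to_array(pdb$xyz, nrow(top), path)
  box <- .parse_cryst1(readLines(path))
  trajectory(top, arr, box = box, stride = stride)
}

.xyzmat_to_array <- function(xyzmat, natoms, path) {
  xyzmat <- as.matrix(xyzmat)
  if (ncol(xyzmat) != 3L * natoms)
    stop("atom count mismatch reading ", path)
  nf <- nrow(xyzmat)
  arr <- array(NA_real_, dim = c(natoms, 3L, nf))
  for (f in seq_len(nf))
    arr[, , f] <- matrix(xyzmat[f, ], ncol = 3L, byrow = TRUE)
  arr
}

#' Write a trajectory to disk
#'
#' Multi-model PDB (one MODEL/ENDMDL pair per frame, CRYST1 box record when a
#' box is present) or a GRO frame series (Angstrom converted back to nm).
#' Round-trips through [read_trajectory()] within format precision
#' (1e-3 Angstrom for PDB).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param format `"auto"`, `"pdb"` or `"gro"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  if (is.null(traj) || n_frames(traj) < 1L) stop("empty trajectory")
  top <- traj$topology
  nf <- n_frames(traj)
  if (format == "pdb") {
    xyzmat <- matrix(NA_real_, nf, 3L * nrow(top))
    for (f in seq_len(nf)) xyzmat[f, ] <- as.vector(t(traj$xyz[, , f]))
    bio3d::write.pdb(file = path, xyz = xyzmat, eleno = top$serial,
                     elety = top$name, resid = top$resname, resno = top$resid,
                     chain = top$chain, elesy = top$element)
    if (!is.null(traj$box)) {
      b <- traj$box[1, ]
      cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       b[1], b[2], b[3], 90, 90, 90)
      writeLines(c(cryst, readLines(path)), path)
    }
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    m <- traj$xyz[, , f] / 10    # Angstrom -> nm
    writeLines(sprintf("frame t=%.3f ps", traj$time[f]), con)
    writeLines(sprintf("%5d", nrow(top)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%9.4f%9.4f%9.4f",
                       top$resid %% 100000L, top$resname, top$name,
                       top$serial %% 100000L, m[, 1], m[, 2], m[, 3]), con)
    b <- if (!is.null(traj$box)) traj$box[f, ] / 10 else c(0, 0, 0)
    writeLines(sprintf("%10.5f%10.5f%10.5f", b[1], b[2], b[3]), con)
  }
  invisible(path)
}
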