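#' Construct a trajectory object
#'
#' A `trajectory` holds an ordered set of frames for a fixed set of particles:
#' coordinates, periodic box vectors and timestamps, in fixed internal units
#' of Angstrom and nanosecond. Only orthorhombic boxes are supported; all
#' lateral analyses in the package work in the XY plane with the membrane
#' normal along z.
#'
#' @param coords numeric array `[n_frames, n_particles, 3]` of wrapped
#'   coordinates in Angstrom.
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param box numeric length-3 vector (constant box) or `[n_frames, 3]` matrix
#'   of box edge lengths in Angstrom.
#' @param unwrapped optional array like `coords` with periodicity removed;
#'   required by mean-squared-displacement analysis (see [unwrap()]).
#' @param atoms optional `data.frame` topology with one row per particle and
#'   columns `atom_name`, `res_id`, `res_name`, `mol_id` (and optionally
#'   `res_uid`, a unique residue-instance counter).
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(coords, times, box, unwrapped = NULL, atoms = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an [n_frames, n_particles, 3] array")
  nf <- dim(coords)[1]
  np <- dim(coords)[2]
  if (length(times) != nf)
    stop("times length (", length(times), ") != n_frames (", nf, ")")
  if (nf >= 2 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  if (!all(is.finite(coords)))
    stop("non-finite coordinates")
  if (is.null(dim(box))) {
    if (length(box) != 3L) stop("box must have 3 edge lengths")
    box <- matrix(box, nrow = nf, ncol = 3L, byrow = TRUE)
  }
  box <- as.matrix(box)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("box must be a length-3 vector or an [n_frames, 3] matrix")
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box edges must be finite and > 0")
  if (!is.null(unwrapped)) {
    if (!identical(dim(unwrapped), dim(coords)))
      stop("unwrapped must have the same dimensions as coords")
    if (!all(is.finite(unwrapped))) stop("non-finite unwrapped coordinates")
  }
  if (!is.null(atoms)) {
    atoms <- as.data.frame(atoms)
    if (nrow(atoms) != np)
      stop("atoms table rows (", nrow(atoms), ") != n_particles (", np, ")")
    need <- c("atom_name", "res_id", "res_name", "mol_id")
    miss <- setdiff(need, names(atoms))
    if (length(miss)) stop("atoms table missing columns: ",
                           paste(miss, collapse = ", "))
    if (is.null(atoms$res_uid)) {
      key <- paste(atoms$mol_id, atoms$res_id, atoms$res_name)
      atoms$res_uid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    }
  }
  structure(list(
    n_particles = np, n_frames = nf,
    coords = coords, unwrapped = unwrapped,
    times = as.numeric(times), box = box, atoms = atoms,
    units = list(length = "angstrom", time = "ns")
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$n_frames, " frames x ", x$n_particles,
      " particles  [", x$units$length, ", ", x$units$time, "]\n", sep = "")
  cat("  time: ", format(x$times[1]), " .. ", format(x$times[x$n_frames]),
      " ns;  box[1]: ", paste(format(x$box[1, ]), collapse = " x "), " A\n",
      sep = "")
  cat("  unwrapped: ", !is.null(x$unwrapped),
      ";  topology: ", !is.null(x$atoms), "\n", sep = "")
  invisible(x)
}

#' Number of frames / particles
#' @param traj a [trajectory()].
#' @return integer count.
#' @export
n_frames <- function(traj) traj$n_frames

#' @rdname n_frames
#' @export
n_particles <- function(traj) traj$n_particles

#' Frame time step
#'
#' Returns the (uniform) frame spacing in ns; errors if spacing varies by
#' more than `tol` relative, since the MSD lag grid assumes uniform sampling.
#' @param traj a [trajectory()].
#' @param tol relative tolerance on spacing uniformity.
#' @return time step in ns.
#' @export
time_step <- function(traj, tol = 1e-6) {
  if (traj$n_frames < 2) stop("need >= 2 frames for a time step")
  dts <- diff(traj$times)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > tol * dt))
    stop("frame times are not uniformly spaced")
  dt
}

#' Remove periodic jumps from a trajectory
#'
#' Accumulates minimum-image frame-to-frame displacements per particle so the
#' unwrapped coordinates are continuous in time. The wrapped view is kept.
#' MSD analysis consumes the unwrapped coordinates only, since wrapping
#' destroys displacement statistics. Idempotent: the unwrapped coordinates
#' are always recomputed from the wrapped view.
#'
#' If an adjusted step exceeds 49% of the box edge the sampling is too sparse
#' for unambiguous unwrapping and a warning is raised.
#'
#' @param traj a [trajectory()].
#' @return the trajectory with `$unwrapped` filled in.
#' @export
unwrap <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- traj$n_frames
  un <- traj$coords
  if (nf >= 2) {
    ambiguous <- FALSE
    for (f in 2:nf) {
      d <- traj$coords[f, , , drop = FALSE] - traj$coords[f - 1L, , , drop = FALSE]
      d <- array(d, dim = dim(d)[2:3])
      L <- traj$box[f - 1L, ]
      d <- d - sweep(round(sweep(d, 2, L, "/")), 2, L, "*")
      if (any(abs(d) > 0.49 * matrix(L, nrow(d), 3, byrow = TRUE)))
        ambiguous <- TRUE
      un[f, , ] <- array(un[f - 1L, , , drop = FALSE], dim = dim(d)) + d
    }
    if (ambiguous)
      warning("frame-to-frame displacements approach half the box edge; ",
              "sampling may be too sparse to unwrap unambiguously")
  }
  traj$unwrapped <- un
  traj
}

#' Write a trajectory in the package columnar text format
#'
#' Plain-text, self-describing format: a header declaring units, particle and
#' frame counts and whether unwrapped coordinates are present, then per frame
#' a `#FRAME` record (index, time, box) followed by one whitespace-separated
#' coordinate row per particle. Coordinates are written with 6 decimals
#' (declared precision 1e-6 Angstrom).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  has_un <- !is.null(traj$unwrapped)
  writeLines(c(
    "#LIPIDLENS_TRJ 1",
    "#length_unit angstrom",
    "#time_unit ns",
    paste("#n_particles", traj$n_particles),
    paste("#n_frames", traj$n_frames),
    paste("#unwrapped", as.integer(has_un))
  ), con)
  for (f in seq_len(traj$n_frames)) {
    writeLines(sprintf("#FRAME %d %.9g %.6f %.6f %.6f", f, traj$times[f],
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
    m <- matrix(traj$coords[f, , ], ncol = 3)
    if (has_un) m <- cbind(m, matrix(traj$unwrapped[f, , ], ncol = 3))
    writeLines(do.call(sprintf,
      c(list(paste(rep("%.6f", ncol(m)), collapse = " ")),
        lapply(seq_len(ncol(m)), function(j) m[, j]))), con)
  }
  invisible(path)
}

# read the package columnar format; errors name the last good frame
.read_columnar <- function(path) {
  lines <- readLines(path)
  hdr <- function(key) {
    ln <- grep(paste0("^#", key, " "), lines, value = TRUE)
    if (!length(ln)) stop("columnar trajectory missing header '#", key, "'")
    strsplit(ln[1], "[[:space:]]+")[[1]][-1]
  }
  if (!grepl("^#LIPIDLENS_TRJ", lines[1]))
    stop("not a lipidlens columnar trajectory: ", path)
  lu <- hdr("length_unit"); tu <- hdr("time_unit")
  if (!identical(lu, "angstrom") || !identical(tu, "ns"))
    stop("unsupported units in header: ", lu, "/", tu)
  np <- as.integer(hdr("n_particles"))
  nf <- as.integer(hdr("n_frames"))
  has_un <- as.integer(hdr("unwrapped")) == 1L
  frame_at <- grep("^#FRAME ", lines)
  coords <- array(NA_real_, c(nf, np, 3))
  unw <- if (has_un) array(NA_real_, c(nf, np, 3)) else NULL
  times <- numeric(nf); box <- matrix(NA_real_, nf, 3)
  ncol_exp <- if (has_un) 6L else 3L
  for (f in seq_len(nf)) {
    ok <- if (f == 1L) "none" else sprintf("frame %d (t = %g ns)", f - 1L,
                                           times[f - 1L])
    if (f > length(frame_at))
      stop("truncated trajectory: expected ", nf, " frames, last good frame: ", ok)
    rec <- strsplit(lines[frame_at[f]], "[[:space:]]+")[[1]]
    times[f] <- as.numeric(rec[3]); box[f, ] <- as.numeric(rec[4:6])
    i0 <- frame_at[f] + 1L
    if (i0 + np - 1L > length(lines))
      stop("truncated trajectory in frame ", f, "; last good frame: ", ok)
    block <- trimws(lines[i0:(i0 + np - 1L)])
    vals <- suppressWarnings(as.numeric(unlist(strsplit(block, "[[:space:]]+"))))
    if (length(vals) != np * ncol_exp || anyNA(vals))
      stop("unparseable coordinate block in frame ", f,
           "; last good frame: ", ok)
    m <- matrix(vals, ncol = ncol_exp, byrow = TRUE)
    coords[f, , ] <- m[, 1:3]
    if (has_un) unw[f, , ] <- m[, 4:6]
  }
  trajectory(coords, times, box, unwrapped = unw)
}

# parse one or more concatenated GRO frames; GRO is in nm -> convert to A.
# returns list(traj, atoms); times taken from 't=' in the title line when
# present, otherwise 0, 1, 2, ... frame indices (ns) with a warning for
# multi-frame files.
.read_gro <- function(path) {
  lines <- readLines(path)
  i <- 1L; frames <- list(); times <- numeric(); boxes <- list(); atoms <- NULL
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("unparseable GRO atom count at line ", i + 1L)
    if (i + 1L + nat + 1L > length(lines))
      stop("truncated GRO file: frame ", length(frames) + 1L, " incomplete")
    at <- lines[(i + 2L):(i + 1L + nat)]
    res_id <- as.integer(substr(at, 1, 5))
    res_name <- trimws(substr(at, 6, 10))
    atom_name <- trimws(substr(at, 11, 15))
    xyz <- matrix(NA_real_, nat, 3)
    xyz[, 1] <- as.numeric(substr(at, 21, 28))
    xyz[, 2] <- as.numeric(substr(at, 29, 36))
    xyz[, 3] <- as.numeric(substr(at, 37, 44))
    if (anyNA(xyz)) stop("unparseable GRO coordinates in frame ",
                         length(frames) + 1L)
    bx <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "[[:space:]]+")[[1]])
    if (length(bx) > 3 && any(abs(bx[4:length(bx)]) > 1e-9))
      stop("triclinic box not supported (off-diagonal box vectors present)")
    tm <- regmatches(title, regexpr("t=\\s*[0-9.eE+-]+", title))
    times <- c(times, if (length(tm))
      as.numeric(sub("t=\\s*", "", tm)) / 1000 else NA_real_)  # GRO t= is ps
    frames[[length(frames) + 1L]] <- xyz * 10       # nm -> Angstrom
    boxes[[length(boxes) + 1L]] <- bx[1:3] * 10
    if (is.null(atoms))
      atoms <- data.frame(atom_name = atom_name, res_id = res_id,
                          res_name = res_name, mol_id = cumsum(
                            c(TRUE, res_id[-1] != res_id[-nat])))
    i <- i + 2L + nat + 1L
  }
  nf <- length(frames)
  if (!nf) stop("empty GRO file: ", path)
  if (anyNA(times)) {
    if (nf > 1L) warning("GRO titles carry no 't=' timestamps; ",
                         "using frame indices as times (ns)")
    times <- seq_len(nf) - 1
  } else times <- times
  coords <- array(NA_real_, c(nf, nrow(atoms), 3))
  box <- matrix(NA_real_, nf, 3)
  for (f in seq_len(nf)) { coords[f, , ] <- frames[[f]]; box[f, ] <- boxes[[f]] }
  trajectory(coords, times, box, atoms = atoms)
}

#' Read a trajectory (topology + coordinates)
#'
#' Supported formats: GRO (single- or multi-frame; nm converted to Angstrom
#' on ingest, `t=` title timestamps in ps converted to ns), PDB topology via
#' \pkg{bio3d}, DCD coordinates via \pkg{bio3d}, and the package's columnar
#' text format (self-describing, see [write_trajectory()]). XTC is not
#' supported; convert to DCD or columnar text first. Triclinic boxes are
#' rejected: all analyses here are lateral (XY) on orthorhombic bilayer
#' boxes.
#'
#' DCD files carry no unit or time metadata, so `units` must be supplied:
#' `list(length = "angstrom"|"nm", dt = <ns per frame>)`. Omitting it is a
#' hard error rather than a silent default.
#'
#' @param topology_path GRO or PDB file defining particles, or a columnar
#'   trajectory (then `coords_path` is ignored).
#' @param coords_path optional DCD (or second GRO) coordinate file.
#' @param units list with `length` and `dt` for formats without metadata.
#' @return a [trajectory()] with a topology table attached where available.
#' @export
read_trajectory <- function(topology_path, coords_path = NULL, units = NULL) {
  if (!file.exists(topology_path)) stop("no such file: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  if (ext %in% c("trj", "txt", "dat"))
    return(.read_columnar(topology_path))
  top <- switch(ext,
    gro = .read_gro(topology_path),
    pdb = {
      p <- bio3d::read.pdb(topology_path)
      at <- data.frame(atom_name = p$atom$elety, res_id = p$atom$resno,
                       res_name = p$atom$resid, mol_id = cumsum(
                         c(TRUE, p$atom$resno[-1] != p$atom$resno[-nrow(p$atom)])))
      xyz <- matrix(p$xyz, ncol = 3, byrow = TRUE)
      co <- array(NA_real_, c(1, nrow(at), 3)); co[1, , ] <- xyz
      trajectory(co, 0, c(1e6, 1e6, 1e6), atoms = at)
    },
    stop("unsupported topology format: .", ext)
  )
  if (is.null(coords_path)) return(top)
  if (!file.exists(coords_path)) stop("no such file: ", coords_path)
  cext <- tolower(tools::file_ext(coords_path))
  if (cext == "xtc")
    stop("XTC is not supported; convert to DCD or the columnar text format")
  if (cext == "gro") {
    tr <- .read_gro(coords_path)
    tr$atoms <- top$atoms
    if (tr$n_particles != top$n_particles)
      stop("particle count mismatch: topology has ", top$n_particles,
           ", coordinates have ", tr$n_particles)
    return(tr)
  }
  if (cext != "dcd") stop("unsupported coordinate format: .", cext)
  if (is.null(units) || is.null(units$length) || is.null(units$dt))
    stop("DCD carries no unit metadata; supply units = list(length=, dt=) ",
         "(no silent default)")
  scale <- switch(units$length, angstrom = 1, nm = 10,
                  stop("unknown length unit: ", units$length))
  dcd <- bio3d::read.dcd(coords_path, verbose = FALSE)
  nf <- nrow(dcd); np <- ncol(dcd) / 3
  if (np != top$n_particles)
    stop("particle count mismatch: topology has ", top$n_particles,
         ", DCD has ", np)
  co <- array(NA_real_, c(nf, np, 3))
  for (f in seq_len(nf)) co[f, , ] <- matrix(dcd[f, ], ncol = 3,
                                             byrow = TRUE) * scale
  bx <- if (is.null(units$box)) rep(1e6, 3) else units$box
  trajectory(co, (seq_len(nf) - 1) * units$dt, bx, atoms = top$atoms)
}

#' Write a single-frame GRO file
#'
#' Coordinates are converted from the internal Angstrom to GRO's nm; the
#' frame time (ns) is recorded as `t=` in ps on the title line.
#'
#' @param traj a [trajectory()] with a topology table.
#' @param path output path.
#' @param frame which frame to write.
#' @return `path`, invisibly.
#' @export
write_gro <- function(traj, path, frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$atoms)) stop("trajectory has no topology table")
  a <- traj$atoms
  xyz <- matrix(traj$coords[frame, , ], ncol = 3) / 10
  lines <- c(
    sprintf("lipidlens frame %d t= %.4f", frame, traj$times[frame] * 1000),
    sprintf("%5d", traj$n_particles),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            a$res_id %% 100000L, substr(a$res_name, 1, 5),
            substr(a$atom_name, 1, 5), seq_len(nrow(a)) %% 100000L,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    sprintf("%10.5f%10.5f%10.5f", traj$box[frame, 1] / 10,
            traj$box[frame, 2] / 10, traj$box[frame, 3] / 10)
  )
  writeLines(lines, path)
  invisible(path)
}
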