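#' Minimum-image distance in a periodic box
#'
#' Euclidean distance between points measured to the nearest periodic image,
#' for orthorhombic boxes. Works in any dimension implied by the inputs
#' (2-D for lateral analyses, 3-D otherwise). Vectorised over rows when `a`
#' and `b` are matrices.
#'
#' @param a,b numeric vectors (one point each) or matrices of points (rows).
#' @param box numeric vector of box edge lengths matching the point
#'   dimension.
#' @return numeric distance(s); always `<=` half the box diagonal.
#' @export
min_image_distance <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  if (ncol(a) != ncol(b) || ncol(a) != length(box))
    stop("dimension mismatch between points and box")
  if (any(!is.finite(box)) || any(box <= 0)) stop("invalid box")
  d <- a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE]
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  unname(sqrt(rowSums(d * d)))
}

# full minimum-image distance matrix between point sets (rows), orthorhombic
.min_image_dist_matrix <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  out <- matrix(0, n, m)
  for (k in seq_along(box)) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

#' Radial region model for the membrane plane
#'
#' Defines, per frame, the two lateral regions the diffusion analysis needs:
#' "complex" (XY distance to the protein centre below `r_complex`) and
#' "bulk" (beyond `r_bulk`). Points in the shell between the radii belong to
#' neither, so boundary-crossers contaminate neither diffusion estimate.
#'
#' @param center length-2 XY point (Angstrom), or an `[n_frames, 2]` matrix
#'   for a mobile protein centre.
#' @param r_complex radius (Angstrom) of the "within complex" cylinder.
#' @param r_bulk radius beyond which a molecule counts as bulk membrane;
#'   must exceed `r_complex`.
#' @return an object of class `region_model`.
#' @export
region_model <- function(center, r_complex, r_bulk) {
  if (!is.finite(r_complex) || !is.finite(r_bulk) || r_complex <= 0)
    stop("radii must be finite and positive")
  if (r_bulk <= r_complex) stop("r_bulk must exceed r_complex")
  center <- rbind(center)
  if (ncol(center) != 2) stop("center must be XY (2-D)")
  structure(list(center = center, r_complex = r_complex, r_bulk = r_bulk,
                 mode = "radial"), class = "region_model")
}

#' Derive a region model from the protein beads of a trajectory
#'
#' The protein XY centre is computed per frame; `r_complex` defaults to the
#' maximum radial extent of the protein beads from that centre (over all
#' frames) and `r_bulk` to `r_complex + pad`.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result with a non-empty protein group.
#' @param pad shell width (Angstrom) separating complex from bulk.
#' @return a [region_model()].
#' @export
region_model_from_protein <- function(traj, sel, pad = 10) {
  if (!length(sel$protein)) stop("protein group is empty")
  xy <- traj$coords[, sel$protein, 1:2, drop = FALSE]
  center <- apply(xy, c(1, 3), mean)
  rmax <- 0
  for (f in seq_len(traj$n_frames)) {
    d <- sweep(matrix(xy[f, , ], ncol = 2), 2, center[f, ])
    rmax <- max(rmax, sqrt(max(rowSums(d * d))))
  }
  region_model(center, rmax, rmax + pad)
}

#' Classify TG molecules into lateral regions per window
#'
#' Splits the trajectory into consecutive non-overlapping windows of
#' `window` frames (a trailing partial window is dropped) and assigns each
#' TG molecule, per window, to `"complex"` if its glycerol-bead XY position
#' stays within `r_complex` of the protein centre for every frame of the
#' window, `"bulk"` if it stays beyond `r_bulk` throughout, and
#' `"excluded"` otherwise. Whole-window membership is deliberately strict:
#' molecules that cross a region boundary mid-window would otherwise mix the
#' two diffusion regimes.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result.
#' @param model a [region_model()].
#' @param window window length in frames (`>= 2`).
#' @return `data.frame` with columns `molecule`, `window`, `frame_start`,
#'   `frame_end`, `category`; category counts in `attr(, "counts")`.
#' @export
classify_regions <- function(traj, sel, model, window) {
  stopifnot(inherits(model, "region_model"))
  if (window < 2) stop("window must span at least 2 frames")
  box_xy <- traj$box[, 1:2, drop = FALSE]
  if (model$r_bulk > min(box_xy) / 2)
    stop("r_bulk (", model$r_bulk, " A) exceeds half the smallest box edge")
  cen <- model$center
  if (nrow(cen) == 1L) cen <- cen[rep(1L, traj$n_frames), , drop = FALSE]
  if (nrow(cen) != traj$n_frames)
    stop("region model center must be one point or one per frame")
  gl <- .glycerol_centroids(traj, sel, dims = 2L)
  mols <- as.integer(dimnames(gl)[[2]])
  nw <- traj$n_frames %/% window
  if (nw < 1) stop("trajectory shorter than one window")
  # radial distance of every molecule to the centre, per frame (min image)
  r <- matrix(NA_real_, traj$n_frames, length(mols))
  for (k in 1:2) {
    d <- matrix(gl[, , k], nrow = traj$n_frames) - cen[, k]
    d <- d - box_xy[, k] * round(d / box_xy[, k])
    r <- if (k == 1) d * d else r + d * d
  }
  r <- sqrt(r)
  out <- vector("list", nw)
  for (w in seq_len(nw)) {
    f0 <- (w - 1L) * window + 1L; f1 <- w * window
    rw <- r[f0:f1, , drop = FALSE]
    inside <- apply(rw < model$r_complex, 2, all)
    outside <- apply(rw > model$r_bulk, 2, all)
    cat_w <- ifelse(inside, "complex", ifelse(outside, "bulk", "excluded"))
    out[[w]] <- data.frame(molecule = mols, window = w,
                           frame_start = f0, frame_end = f1,
                           category = cat_w)
  }
  res <- do.call(rbind, out)
  counts <- table(factor(res$category,
                         levels = c("complex", "bulk", "excluded")))
  attr(res, "counts") <- counts
  attr(res, "window") <- window
  res
}

#' Tilt angle of a residue-residue vector against the membrane normal
#'
#' For each frame, takes the centroid of each residue's particles, forms the
#' minimum-image vector from residue `a` to residue `b`, and reports the
#' angle against the membrane normal (box z-axis by default, the standard
#' bilayer convention). The default is the unsigned form
#' `acos(|v.n| / |v|)` in `[0, 90]` degrees; `signed = TRUE` gives
#' `acos(v.n / |v|)` in `[0, 180]`.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result.
#' @param residue_a,residue_b residue selectors: numeric IDs or strings like
#'   `"SER126"`.
#' @param normal membrane normal (unit length not required).
#' @param signed logical; report the signed (non-absolute) angle.
#' @return `data.frame` (class `angle_series`) with columns `time`, `theta`
#'   (degrees).
#' @export
tilt_angle <- function(traj, sel, residue_a, residue_b,
                       normal = c(0, 0, 1), signed = FALSE) {
  pick <- function(r) {
    if (is.numeric(r)) idx <- which(sel$res_id == r)
    else {
      m <- regmatches(r, regexec("^([A-Za-z]+)([0-9]+)$", r))[[1]]
      if (length(m) != 3) stop("cannot parse residue selector '", r, "'")
      idx <- which(toupper(sel$res_name) == toupper(m[2]) &
                     sel$res_id == as.integer(m[3]))
    }
    if (!length(idx)) stop("residue '", r, "' resolves to no particles")
    idx
  }
  ia <- pick(residue_a); ib <- pick(residue_b)
  n <- normal / sqrt(sum(normal^2))
  ca <- apply(traj$coords[, ia, , drop = FALSE], c(1, 3), mean)
  cb <- apply(traj$coords[, ib, , drop = FALSE], c(1, 3), mean)
  v <- cb - ca
  v <- v - traj$box * round(v / traj$box)
  len <- sqrt(rowSums(v * v))
  if (any(len < 1e-12))
    stop("zero-length residue-residue vector at frame ",
         which(len < 1e-12)[1], "; angle undefined")
  proj <- as.vector(v %*% n) / len
  proj <- pmax(-1, pmin(1, proj))
  theta <- if (signed) acos(proj) else acos(abs(proj))
  structure(data.frame(time = traj$times, theta = theta * 180 / pi),
            class = c("angle_series", "data.frame"),
            residues = c(a = as.character(residue_a),
                         b = as.character(residue_b)),
            normal = n, signed = signed)
}
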