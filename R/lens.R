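#' Single-linkage clustering of TG molecules in one frame
#'
#' Connected components of the graph linking TG glycerol-bead centroids
#' whose minimum-image distance is at most `cutoff` — the single-linkage
#' definition of a TG aggregate. Clustering is 3-D by default since a
#' nascent lens thickens the bilayer locally; `dims = "xy"` projects onto
#' the membrane plane. Labels are deterministic: clusters are numbered by
#' decreasing size, ties broken by the lowest molecule ID they contain.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result.
#' @param frame frame index.
#' @param cutoff linkage cutoff (Angstrom), `> 0`.
#' @param dims `"xyz"` or `"xy"`.
#' @return integer cluster labels named by molecule ID; cluster sizes in
#'   `attr(, "sizes")`.
#' @export
cluster_tg <- function(traj, sel, frame = 1L, cutoff = 12,
                       dims = c("xyz", "xy")) {
  dims <- match.arg(dims)
  if (cutoff <= 0) stop("cutoff must be > 0")
  nd <- if (dims == "xy") 2L else 3L
  gl <- .glycerol_centroids(traj, sel, dims = nd)
  mols <- as.integer(dimnames(gl)[[2]])
  pts <- matrix(gl[frame, , ], ncol = nd)
  n <- nrow(pts)
  dm <- .min_image_dist_matrix(pts, pts, traj$box[frame, seq_len(nd)])
  # connected components by breadth-first traversal of the adjacency
  lab <- integer(n); comp <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    comp <- comp + 1L
    queue <- i; lab[i] <- comp
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- which(dm[j, ] <= cutoff & lab == 0L)
      lab[nb] <- comp
      queue <- c(queue, nb)
    }
  }
  # deterministic relabel: by size desc, ties by lowest member molecule ID
  sizes <- tabulate(lab, comp)
  first_mol <- vapply(seq_len(comp), function(k) min(mols[lab == k]), 0L)
  ord <- order(-sizes, first_mol)
  relab <- match(lab, ord)
  out <- structure(relab, names = as.character(mols),
                   sizes = sizes[ord], cutoff = cutoff, dims = dims)
  out
}

#' TG coalescence (lens nucleation) detection over a trajectory
#'
#' Clusters the TG molecules in every frame with [cluster_tg()] and reports
#' the largest-cluster size, cluster count and — when a chamber annulus is
#' given — the fraction of largest-cluster molecules lying inside the
#' chamber (XY radial distance to the chamber centre between `r_inner` and
#' `r_outer`). The verdict is `"phase-separated"` when the largest cluster
#' holds more than `threshold` of all TG molecules in every frame of the
#' sustained span (the final `span_frac` of frames), else `"dispersed"`.
#' The reported onset frame is the first frame from which the threshold
#' holds uninterruptedly to the end. All thresholds are operational
#' definitions (coalescence has no unique quantitative criterion) and are
#' echoed in the result.
#'
#' @param traj a [trajectory()].
#' @param sel a [build_selection()] result.
#' @param cutoff single-linkage cutoff (Angstrom).
#' @param chamber optional `list(center = c(x, y), r_inner, r_outer)`.
#' @param threshold largest-cluster fraction defining coalescence.
#' @param span_frac final fraction of frames that must sustain it.
#' @param dims `"xyz"` or `"xy"` (see [cluster_tg()]).
#' @return `data.frame` of class `cluster_series` with columns `time`,
#'   `largest`, `largest_frac`, `n_clusters`, `chamber_frac`; attributes
#'   `verdict`, `onset_frame` (NA when dispersed) and the settings.
#' @export
nucleation_series <- function(traj, sel, cutoff = 12, chamber = NULL,
                              threshold = 0.5, span_frac = 0.2,
                              dims = c("xyz", "xy")) {
  dims <- match.arg(dims)
  nf <- traj$n_frames
  n_tg <- length(.tg_molecules(sel))
  largest <- integer(nf); ncl <- integer(nf); chfr <- rep(NA_real_, nf)
  gl2 <- .glycerol_centroids(traj, sel, dims = 2L)
  for (f in seq_len(nf)) {
    lab <- cluster_tg(traj, sel, frame = f, cutoff = cutoff, dims = dims)
    sizes <- attr(lab, "sizes")
    largest[f] <- sizes[1]
    ncl[f] <- length(sizes)
    if (!is.null(chamber)) {
      mem <- which(lab == 1L)
      xy <- matrix(gl2[f, mem, ], ncol = 2)
      r <- min_image_distance(xy, chamber$center, traj$box[f, 1:2])
      chfr[f] <- mean(r >= chamber$r_inner & r <= chamber$r_outer)
    }
  }
  frac <- largest / n_tg
  span0 <- nf - ceiling(span_frac * nf) + 1L
  separated <- all(frac[span0:nf] > threshold)
  onset <- NA_integer_
  if (separated) {
    ok <- rev(cumprod(rev(frac > threshold))) == 1  # holds to the end
    onset <- which(ok)[1]
  }
  structure(data.frame(time = traj$times, largest = largest,
                       largest_frac = frac, n_clusters = ncl,
                       chamber_frac = chfr),
            class = c("cluster_series", "data.frame"),
            verdict = if (separated) "phase-separated" else "dispersed",
            onset_frame = onset, cutoff = cutoff, threshold = threshold,
            span_frac = span_frac, dims = dims, n_tg = n_tg)
}

#' @export
print.cluster_series <- function(x, ...) {
  cat("<cluster_series> ", nrow(x), " frames, ", attr(x, "n_tg"),
      " TG molecules, linkage cutoff ", attr(x, "cutoff"), " A\n", sep = "")
  cat("  verdict: ", attr(x, "verdict"),
      if (!is.na(attr(x, "onset_frame")))
        paste0(" (onset frame ", attr(x, "onset_frame"), ")"), "\n", sep = "")
  invisible(x)
}
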