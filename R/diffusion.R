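# Time-origin-averaged squared-displacement sums for one segment.
#
# For a 1-D signal x of length N the quantity
#   S(tau) = sum_t (x(t+tau) - x(t))^2,  t = 1..N-tau
# is computed for all lags at O(N log N) via the standard FFT decomposition
#   S(tau) = S1(tau) - 2*AC(tau)
# where AC is the unnormalised autocorrelation and S1 follows a two-sided
# running-sum recursion. Returns per-lag sums and sample counts so segments
# can be pooled before averaging.
.msd_sums_1d <- function(x) {
  n <- length(x)
  len <- 2^ceiling(log2(2 * n))
  fx <- stats::fft(c(x, numeric(len - n)))
  ac <- Re(stats::fft(fx * Conj(fx), inverse = TRUE))[seq_len(n)] / len
  d <- x * x
  q <- 2 * sum(d)
  s1 <- numeric(n)
  s1[1] <- q
  for (m in seq_len(n - 1)) {
    q <- q - d[m] - d[n - m + 1L]
    s1[m + 1L] <- q
  }
  s1 - 2 * ac
}

# squared-displacement sums for an XY segment (rows = frames)
.msd_sums_xy <- function(xy, max_lag) {
  n <- nrow(xy)
  s <- .msd_sums_1d(xy[, 1]) + .msd_sums_1d(xy[, 2])
  lag <- seq_len(min(max_lag + 1L, n)) - 1L
  list(ss = s[lag + 1L], n = n - lag)
}

#' Time-origin-averaged mean squared displacement
#'
#' Lateral (2-D XY) MSD of the TG glycerol-bead centroids, averaged over all
#' molecules of a category and all time origins:
#' `MSD(tau) = < |r(t0 + tau) - r(t0)|^2 >` with every frame used as an
#' origin. Computed from unwrapped coordinates only — wrapped coordinates
#' destroy displacement statistics — via an FFT decomposition equivalent to
#' the brute-force double loop.
#'
#' When `assignments` (from [classify_regions()]) is given, each
#' molecule-window segment contributes to its category's curve and
#' displacements never straddle window boundaries; molecules classified
#' `"excluded"` contribute to no curve. Without assignments a single
#' `"all"` curve over the whole trajectory is returned.
#'
#' @param traj a [trajectory()] with unwrapped coordinates.
#' @param sel optional [build_selection()] result; `NULL` treats every
#'   particle as one molecule.
#' @param assignments optional [classify_regions()] table.
#' @param max_lag maximum lag in frames (default: half the segment length).
#' @return named list of `msd_curve` objects (`data.frame`s with `lag` in
#'   ns, `msd` in Angstrom^2, `n` samples), one per category. Empty
#'   categories are omitted with a warning.
#' @export
msd <- function(traj, sel = NULL, assignments = NULL, max_lag = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$unwrapped))
    stop("MSD needs unwrapped coordinates; call unwrap() first")
  dt <- time_step(traj)
  if (is.null(sel)) {
    gl <- traj$unwrapped[, , 1:2, drop = FALSE]
    mols <- seq_len(traj$n_particles)
  } else {
    gl <- .glycerol_centroids(traj, sel, dims = 2L, unwrapped = TRUE)
    mols <- as.integer(dimnames(gl)[[2]])
  }
  if (is.null(assignments)) {
    assignments <- data.frame(molecule = mols, window = 1L,
                              frame_start = 1L, frame_end = traj$n_frames,
                              category = "all")
  }
  cats <- setdiff(unique(assignments$category), "excluded")
  out <- list()
  for (cat_k in cats) {
    rows <- assignments[assignments$category == cat_k, , drop = FALSE]
    if (!nrow(rows)) next
    seg_len <- rows$frame_end - rows$frame_start + 1L
    ml <- if (is.null(max_lag)) max(1L, floor(min(seg_len) / 2)) else
      as.integer(max_lag)
    ss <- numeric(ml + 1L); nn <- numeric(ml + 1L)
    for (i in seq_len(nrow(rows))) {
      m <- match(rows$molecule[i], mols)
      if (is.na(m)) stop("assignment names unknown molecule ",
                         rows$molecule[i])
      xy <- matrix(gl[rows$frame_start[i]:rows$frame_end[i], m, ], ncol = 2)
      s <- .msd_sums_xy(xy, ml)
      k <- seq_along(s$ss)
      ss[k] <- ss[k] + s$ss
      nn[k] <- nn[k] + s$n
    }
    keep <- nn > 0
    curve <- data.frame(lag = (which(keep) - 1L) * dt,
                        msd = pmax((ss / pmax(nn, 1))[keep], 0),
                        n = nn[keep])
    curve$msd[1] <- 0            # lag-0 MSD is identically zero
    out[[cat_k]] <- structure(curve,
                              class = c("msd_curve", "data.frame"),
                              category = cat_k, dt = dt,
                              segment_min_frames = min(seg_len))
  }
  if (any(assignments$category %in%
          c("complex", "bulk", "excluded")))     # region-classified input
    for (m in setdiff(c("complex", "bulk"), names(out)))
      warning("category '", m, "' has no molecules; curve omitted")
  out
}

#' Fit a lateral diffusion coefficient to an MSD curve
#'
#' Ordinary least-squares fit of MSD against lag over `fit_window`
#' (`c(lag_min, lag_max)` in ns), intercept free; for 2-D lateral motion
#' `D = slope / 4`. The default window spans 10%–50% of the shortest
#' contiguous segment that produced the curve: the early part of the curve
#' is kept away from lag zero and the long-lag tail, where few origin pairs
#' remain and the curve is noisy, is excluded.
#'
#' @param curve an `msd_curve` from [msd()].
#' @param fit_window `c(lag_min, lag_max)` in ns, or `NULL` for the default.
#' @return object of class `diffusion_result`: `d` (Angstrom^2/ns), `d_se`
#'   (standard error of the OLS slope / 4), `intercept`, `r_squared`,
#'   `fit_window`, `category`.
#' @export
fit_diffusion <- function(curve, fit_window = NULL) {
  stopifnot(inherits(curve, "msd_curve"))
  dt <- attr(curve, "dt")
  if (is.null(fit_window)) {
    w <- attr(curve, "segment_min_frames")
    if (is.null(w)) w <- max(curve$lag) / dt + 1
    fit_window <- c(0.1, 0.5) * w * dt
  }
  if (fit_window[1] >= fit_window[2]) stop("empty fit window")
  sub <- curve[curve$lag >= fit_window[1] & curve$lag <= fit_window[2], ]
  if (nrow(sub) < 3)
    stop("fewer than 3 lag points inside the fit window [",
         fit_window[1], ", ", fit_window[2], "] ns")
  fit <- stats::lm(msd ~ lag, data = sub)
  sm <- summary(fit)
  slope <- stats::coef(fit)[["lag"]]
  se <- sm$coefficients["lag", "Std. Error"]
  structure(list(d = slope / 4, d_se = se / 4,
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r_squared = sm$r.squared,
                 fit_window = fit_window,
                 category = attr(curve, "category")),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("D(", x$category, ") = ", format(x$d, digits = 4), " +/- ",
      format(x$d_se, digits = 2), " A^2/ns   (R^2 = ",
      format(x$r_squared, digits = 4), ", window ",
      format(x$fit_window[1]), "-", format(x$fit_window[2]), " ns)\n",
      sep = "")
  invisible(x)
}

#' Fold reduction between bulk and complex diffusion
#'
#' Ratio `d_bulk / d_complex` with first-order uncertainty propagation from
#' the two OLS slope standard errors.
#'
#' @param res_bulk,res_complex [fit_diffusion()] results.
#' @return list with `ratio` and `se`.
#' @export
fold_reduction <- function(res_bulk, res_complex) {
  if (!is.finite(res_complex$d) || res_complex$d <= 0)
    stop("complex diffusion coefficient must be > 0")
  if (!is.finite(res_bulk$d) || res_bulk$d <= 0)
    stop("bulk diffusion coefficient must be > 0")
  ratio <- res_bulk$d / res_complex$d
  se <- ratio * sqrt((res_bulk$d_se / res_bulk$d)^2 +
                       (res_complex$d_se / res_complex$d)^2)
  list(ratio = ratio, se = se)
}

#' Region-partitioned diffusion analysis
#'
#' Convenience wrapper chaining [classify_regions()], [msd()] and
#' [fit_diffusion()] for the `"complex"` and `"bulk"` categories, then
#' [fold_reduction()].
#'
#' @param traj a [trajectory()] (unwrapped on the fly if needed).
#' @param sel a [build_selection()] result.
#' @param model a [region_model()].
#' @param window classification window in frames.
#' @param max_lag,fit_window passed to [msd()] / [fit_diffusion()].
#' @return list with `assignments`, `curves`, `fits`, `fold` and the
#'   settings used.
#' @export
diffusion_analysis <- function(traj, sel, model, window,
                               max_lag = NULL, fit_window = NULL) {
  if (is.null(traj$unwrapped)) traj <- unwrap(traj)
  asg <- classify_regions(traj, sel, model, window)
  curves <- msd(traj, sel, asg, max_lag = max_lag)
  fits <- lapply(curves, fit_diffusion, fit_window = fit_window)
  fold <- if (!is.null(fits$bulk) && !is.null(fits$complex))
    fold_reduction(fits$bulk, fits$complex) else NULL
  list(assignments = asg, curves = curves, fits = fits, fold = fold,
       settings = list(window = window, max_lag = max_lag,
                       fit_window = fit_window,
                       r_complex = model$r_complex, r_bulk = model$r_bulk))
}
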