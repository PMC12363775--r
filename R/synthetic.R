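#' Configuration for the Brownian trap generator
#'
#' Parameters of a 2-D lateral Brownian-dynamics generator with an optional
#' circular "trap" region of distinct diffusion coefficient, emulating the
#' two diffusion regimes of TG in a protein-laden bilayer: fast in the bulk
#' membrane, slow within the protein complex. The two coefficients are the
#' ground truth recovered by the diffusion module in tests.
#'
#' @param n_particles number of independent walkers (each stands for one TG
#'   molecule's glycerol bead).
#' @param box_xy lateral box edges (Angstrom); scalar recycled to both axes.
#' @param dt time per frame (ns).
#' @param n_frames number of frames (`>= 2`).
#' @param d_bulk,d_trap diffusion coefficients (Angstrom^2/ns) outside and
#'   inside the trap disk. `d_trap = 0` freezes trapped particles.
#' @param trap_center XY centre of the trap disk; `NULL` for a homogeneous
#'   (trap-free) membrane.
#' @param trap_radius trap disk radius (Angstrom), `< min(box_xy)/2`.
#' @param n_trap_init number of particles initialised uniformly inside the
#'   trap disk (the rest are uniform over the box); emulates TG already
#'   accumulated within the complex.
#' @param seed RNG seed; a fixed seed gives bit-identical output.
#' @return a validated `brownian_config` list.
#' @export
brownian_config <- function(n_particles, box_xy, dt, n_frames,
                            d_bulk, d_trap = d_bulk, trap_center = NULL,
                            trap_radius = 0, n_trap_init = 0, seed = 1L) {
  box_xy <- rep_len(as.numeric(box_xy), 2L)
  vals <- c(box_xy, dt, n_frames, d_bulk, d_trap, trap_radius)
  if (any(!is.finite(vals))) stop("non-finite generator parameter")
  if (dt <= 0) stop("dt must be > 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (d_bulk < 0 || d_trap < 0) stop("diffusion coefficients must be >= 0")
  if (any(box_xy <= 0)) stop("box edges must be > 0")
  if (!is.null(trap_center)) {
    if (length(trap_center) != 2) stop("trap_center must be XY")
    if (trap_radius <= 0 || trap_radius >= min(box_xy) / 2)
      stop("trap_radius must satisfy 0 < r < min(box_xy)/2")
    if (n_trap_init > n_particles) stop("n_trap_init exceeds n_particles")
  } else if (n_trap_init > 0) stop("n_trap_init requires a trap_center")
  structure(list(n_particles = as.integer(n_particles), box_xy = box_xy,
                 dt = dt, n_frames = as.integer(n_frames),
                 d_bulk = d_bulk, d_trap = d_trap,
                 trap_center = trap_center, trap_radius = trap_radius,
                 n_trap_init = as.integer(n_trap_init),
                 seed = as.integer(seed)), class = "brownian_config")
}

#' Generate a Brownian trajectory with a slow-diffusion trap
#'
#' Each particle performs an independent 2-D Gaussian random walk; the
#' per-axis step variance is `2 * D * dt` with `D = d_trap` when the
#' particle starts the step inside the trap disk (minimum-image XY distance
#' to `trap_center` below `trap_radius`) and `d_bulk` otherwise. There is no
#' reflecting barrier: particles cross the trap boundary freely, as TG
#' enters and leaves a membrane protein complex. Wrapped and unwrapped
#' coordinates are both stored; MSD analysis consumes the unwrapped set.
#'
#' The true parameters are attached as `attr(, "ground_truth")` for test
#' harnesses and can be written to a YAML sidecar with
#' [write_ground_truth()].
#'
#' @param cfg a [brownian_config()].
#' @return a [trajectory()]; particles carry a minimal one-bead-per-molecule
#'   TG topology (`res_name "TG"`, `atom_name "GL"`).
#' @export
gen_brownian_trap <- function(cfg) {
  stopifnot(inherits(cfg, "brownian_config"))
  set.seed(cfg$seed)
  np <- cfg$n_particles; nf <- cfg$n_frames
  L <- cfg$box_xy
  pos <- cbind(stats::runif(np, 0, L[1]), stats::runif(np, 0, L[2]))
  if (cfg$n_trap_init > 0) {
    # uniform over the trap disk for the first n_trap_init particles
    i <- seq_len(cfg$n_trap_init)
    rr <- cfg$trap_radius * sqrt(stats::runif(length(i)))
    th <- stats::runif(length(i), 0, 2 * pi)
    pos[i, 1] <- cfg$trap_center[1] + rr * cos(th)
    pos[i, 2] <- cfg$trap_center[2] + rr * sin(th)
    pos[i, ] <- pos[i, , drop = FALSE] %% matrix(L, length(i), 2, byrow = TRUE)
  }
  sd_bulk <- sqrt(2 * cfg$d_bulk * cfg$dt)
  sd_trap <- sqrt(2 * cfg$d_trap * cfg$dt)
  zc <- 50                              # fixed bilayer mid-plane height
  un <- array(NA_real_, c(nf, np, 3)); wr <- un
  upos <- pos
  un[1, , 1:2] <- upos; un[1, , 3] <- zc
  wr[1, , 1:2] <- pos;  wr[1, , 3] <- zc
  for (f in 2:nf) {
    if (is.null(cfg$trap_center)) {
      sdv <- rep(sd_bulk, np)
    } else {
      r <- min_image_distance(pos, cfg$trap_center, L)
      sdv <- ifelse(r < cfg$trap_radius, sd_trap, sd_bulk)
    }
    step <- matrix(stats::rnorm(2 * np), np, 2) * sdv
    upos <- upos + step
    pos <- upos %% matrix(L, np, 2, byrow = TRUE)
    un[f, , 1:2] <- upos; un[f, , 3] <- zc
    wr[f, , 1:2] <- pos;  wr[f, , 3] <- zc
  }
  atoms <- data.frame(atom_name = "GL", res_id = seq_len(np),
                      res_name = "TG", mol_id = seq_len(np))
  tr <- trajectory(wr, (seq_len(nf) - 1) * cfg$dt, c(L, 100),
                   unwrapped = un, atoms = atoms)
  attr(tr, "ground_truth") <- list(
    d_bulk = cfg$d_bulk, d_trap = cfg$d_trap,
    trap_center = cfg$trap_center, trap_radius = cfg$trap_radius,
    seed = cfg$seed)
  tr
}

#' Configuration for the two-state binding generator
#'
#' @param k_on binding rate per concentration per ns (`> 0`).
#' @param k_off unbinding rate per ns (`> 0`).
#' @param tg_conc TG concentration; the unit (e.g. mol%) is carried verbatim
#'   into the KD estimate.
#' @param dt time per frame (ns).
#' @param n_frames chain length.
#' @param seed RNG seed.
#' @return a validated `two_state_config`; the implied ground truth is
#'   `KD_true = k_off / k_on`.
#' @export
two_state_config <- function(k_on, k_off, tg_conc, dt, n_frames, seed = 1L) {
  if (any(!is.finite(c(k_on, k_off, tg_conc, dt, n_frames))))
    stop("non-finite generator parameter")
  if (k_on <= 0 || k_off <= 0) stop("rates must be > 0")
  if (tg_conc <= 0) stop("tg_conc must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(k_on = k_on, k_off = k_off, tg_conc = tg_conc, dt = dt,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "two_state_config")
}

#' Generate a two-state (bound/unbound) binding series
#'
#' Discrete-time two-state Markov chain with per-frame switching
#' probabilities `1 - exp(-k_on * tg_conc * dt)` (unbound to bound) and
#' `1 - exp(-k_off * dt)` (bound to unbound). The chain is realised exactly
#' through its alternating geometric dwell times, so the cost scales with
#' the number of transitions rather than frames. The initial state is drawn
#' from the chain's stationary distribution. The stationary bound fraction
#' is `p_on / (p_on + p_off)`, which for small per-frame rates approaches
#' `tg_conc / (KD_true + tg_conc)` with `KD_true = k_off / k_on`.
#'
#' @param cfg a [two_state_config()].
#' @return a [binding_series()] with states but no distances; ground truth
#'   in `attr(, "ground_truth")`.
#' @export
gen_two_state <- function(cfg) {
  stopifnot(inherits(cfg, "two_state_config"))
  set.seed(cfg$seed)
  p_on <- 1 - exp(-cfg$k_on * cfg$tg_conc * cfg$dt)
  p_off <- 1 - exp(-cfg$k_off * cfg$dt)
  nf <- cfg$n_frames
  state0 <- stats::rbinom(1, 1, p_on / (p_on + p_off)) == 1L
  states <- logical(0); cur <- state0; total <- 0L
  exp_runs <- ceiling(nf * (p_on * p_off / (p_on + p_off)) * 2) + 10L
  while (total < nf) {
    k <- max(exp_runs, 16L)
    # dwell of the current state then its complement, alternating
    d1 <- stats::rgeom(k, if (cur) p_off else p_on) + 1
    d2 <- stats::rgeom(k, if (cur) p_on else p_off) + 1
    # cap dwells at the series length: frames past nf are discarded anyway
    dw <- pmin(as.vector(rbind(d1, d2)), nf)
    st <- rep(c(cur, !cur), k)
    states <- c(states, rep(st, dw))
    total <- length(states)
    cur <- if (length(st)) !st[length(st)] else cur
  }
  states <- states[seq_len(nf)]
  bs <- binding_series(times = (seq_len(nf) - 1) * cfg$dt, state = states,
                       tg_conc = cfg$tg_conc)
  attr(bs, "ground_truth") <- list(kd_true = cfg$k_off / cfg$k_on,
                                   k_on = cfg$k_on, k_off = cfg$k_off,
                                   seed = cfg$seed)
  bs
}

#' Generate a C11 double-ring toroid fixture
#'
#' Deterministic geometric stand-in for a toroid-shaped membrane protein
#' assembly: an inner ring of `n_protomers` two-helix protomers (default 11,
#' C11 symmetry) at radius `r_inner` and an outer ring at `r_outer`, with
#' the chamber annulus between them. Inner-ring protomers carry residues
#' PHE57, SER61, LEU105, SER109 (plus filler residues) and lumenal-loop
#' residues SER126/SER131 for tilt-angle fixtures; outer-ring protomers
#' carry generic SEI residues. TG molecules (single glycerol bead each) can
#' be seeded in the chamber uniformly or as one planted cluster plus
#' dispersed singletons.
#'
#' @param n_protomers protomers per ring (`>= 3`).
#' @param r_inner,r_outer ring radii (Angstrom), `r_inner < r_outer`.
#' @param box box edge lengths (Angstrom), length 3.
#' @param n_tg number of TG molecules to seed (0 for protein only).
#' @param tg_mode `"uniform"` (spread over the chamber annulus with a
#'   minimum pairwise separation of `min_sep`, emulating TG dissolved in
#'   the bilayer below its demixing concentration) or `"clustered"`
#'   (`cluster_frac` of the TG in one tight blob at the chamber mid-radius,
#'   the rest spread far apart outside the protein).
#' @param cluster_frac fraction of TG in the planted cluster.
#' @param cluster_sd Gaussian spread (Angstrom) of the planted cluster.
#' @param min_sep minimum TG-TG separation (Angstrom) in uniform mode,
#'   enforced by dart throwing; keeps a dispersed fixture dispersed under
#'   the default 12 Angstrom linkage cutoff.
#' @param n_frames number of (identical) frames to emit.
#' @param seed RNG seed for the TG placement.
#' @return list with `traj` (a [trajectory()]), `sel` (a selection set),
#'   `chamber` (`list(center, r_inner, r_outer)`) and `ground_truth`
#'   (planted cluster members, if any).
#' @export
gen_toroid <- function(n_protomers = 11L, r_inner = 30, r_outer = 60,
                       box = c(200, 200, 100), n_tg = 0L,
                       tg_mode = c("uniform", "clustered"),
                       cluster_frac = 0.6, cluster_sd = 3, min_sep = 13,
                       n_frames = 1L, seed = 1L) {
  tg_mode <- match.arg(tg_mode)
  if (n_protomers < 3) stop("need at least 3 protomers for a ring")
  if (r_inner >= r_outer) stop("r_inner must be < r_outer")
  cx <- box[1] / 2; cy <- box[2] / 2; zc <- box[3] / 2
  inner_res <- data.frame(
    res_id = c(50, 57, 61, 70, 90, 105, 109, 120, 126, 131),
    res_name = c("ALA", "PHE", "SER", "ALA", "GLY", "LEU", "SER", "GLY",
                 "SER", "SER"),
    helix = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  outer_res <- data.frame(res_id = 201:206, res_name = "SEI",
                          helix = rep(c(1, 2), each = 3))
  rows <- list(); coords <- list()
  add_ring <- function(resdf, radius, ring_tag) {
    for (p in seq_len(n_protomers)) {
      a0 <- 2 * pi * (p - 1) / n_protomers
      for (i in seq_len(nrow(resdf))) {
        h <- resdf$helix[i]
        # helices at +/- 4 deg around the protomer axis; lumenal loop
        # residues (helix 3) sit above the membrane at a radial offset
        ang <- a0 + c(-1, 1, 0)[h] * (4 * pi / 180)
        rad <- radius + if (h == 3) c(0, 5)[match(resdf$res_id[i],
                                                  c(126, 131))] else 0
        z <- if (h == 3) zc + 25 + 8 * (resdf$res_id[i] == 131)
             else zc - 20 + 4 * (i %% 10)
        rows[[length(rows) + 1L]] <<- data.frame(
          atom_name = "BB", res_id = resdf$res_id[i],
          res_name = resdf$res_name[i],
          mol_id = 1000L + ring_tag * 100L + p)
        coords[[length(coords) + 1L]] <<-
          c(cx + rad * cos(ang), cy + rad * sin(ang), z)
      }
    }
  }
  add_ring(inner_res, r_inner, 1L)
  add_ring(outer_res, r_outer, 2L)
  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  gt <- list()
  if (n_tg > 0) {
    set.seed(seed)
    rmid <- (r_inner + r_outer) / 2
    if (tg_mode == "uniform") {
      tg_xy <- matrix(NA_real_, 0, 2)
      tries <- 0L
      while (nrow(tg_xy) < n_tg) {
        if ((tries <- tries + 1L) > 200L * n_tg)
          stop("cannot place ", n_tg, " TG with min_sep ", min_sep,
               " A in the chamber annulus; lower n_tg or min_sep")
        rr <- sqrt(stats::runif(1, r_inner^2, r_outer^2))
        th <- stats::runif(1, 0, 2 * pi)
        p <- c(cx + rr * cos(th), cy + rr * sin(th))
        if (!nrow(tg_xy) ||
            min(sqrt(colSums((t(tg_xy) - p)^2))) >= min_sep)
          tg_xy <- rbind(tg_xy, p)
      }
      rownames(tg_xy) <- NULL
    } else {
      n_cl <- round(cluster_frac * n_tg)
      cl <- cbind(cx + rmid + stats::rnorm(n_cl, 0, cluster_sd),
                  cy + stats::rnorm(n_cl, 0, cluster_sd))
      n_disp <- n_tg - n_cl
      # dispersed singletons on a sparse grid well outside the toroid
      g <- ceiling(sqrt(n_disp))
      gx <- (seq_len(g) - 0.5) * box[1] / g
      grid <- as.matrix(expand.grid(gx, gx))[seq_len(n_disp), , drop = FALSE]
      keep_away <- sqrt((grid[, 1] - cx)^2 + (grid[, 2] - cy)^2) > r_outer + 15
      grid[!keep_away, ] <- cbind(5 + 30 * seq_len(sum(!keep_away)) %% box[1],
                                  5)
      tg_xy <- rbind(cl, grid)
      gt$cluster_members <- seq_len(n_cl)
    }
    tg_atoms <- data.frame(atom_name = "GL",
                           res_id = seq_len(n_tg),
                           res_name = "TG", mol_id = seq_len(n_tg))
    atoms <- rbind(tg_atoms, atoms)
    xyz <- rbind(cbind(tg_xy, zc), xyz)
  }
  np <- nrow(atoms)
  co <- array(NA_real_, c(n_frames, np, 3))
  for (f in seq_len(n_frames)) co[f, , ] <- xyz
  tr <- trajectory(co, seq_len(n_frames) - 1, box, atoms = atoms)
  sel <- if (n_tg > 0)
    build_selection(list(tg = list(resname = "TG")), atoms) else NULL
  chamber <- list(center = c(cx, cy), r_inner = r_inner, r_outer = r_outer)
  attr(tr, "ground_truth") <- gt
  list(traj = tr, sel = sel, chamber = chamber, ground_truth = gt)
}

#' Write a YAML ground-truth sidecar for a synthetic object
#'
#' @param x a synthetic trajectory or binding series carrying a
#'   `ground_truth` attribute.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(x, path) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) stop("object carries no ground truth")
  yaml::write_yaml(gt, path)
  invisible(path)
}
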