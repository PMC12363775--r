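# Independent brute-force oracles and hand-built fixtures. These stay
# deliberately naive (O(n^2) loops, explicit image enumeration) so they are
# not the code paths they check.

# minimum-image distance by enumerating all 27 periodic images
oracle_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- a - (b + c(i, j, k) * box)
    best <- min(best, sqrt(sum(d * d)))
  }
  best
}

# time-origin-averaged 2-D MSD by the O(n^2) double loop
oracle_msd <- function(xy, max_lag) {
  n <- nrow(xy)
  out <- numeric(max_lag + 1)
  for (tau in 0:max_lag) {
    acc <- 0
    for (t0 in seq_len(n - tau)) {
      d <- xy[t0 + tau, ] - xy[t0, ]
      acc <- acc + sum(d * d)
    }
    out[tau + 1] <- acc / (n - tau)
  }
  out
}

# all-pairs logistic interaction score per residue uid, explicit loops
oracle_interaction <- function(tg, pr, res_uid, box, scale = 0.5) {
  uids <- unique(res_uid)
  s <- setNames(numeric(length(uids)), uids)
  for (i in seq_len(nrow(tg))) for (j in seq_len(nrow(pr))) {
    r <- oracle_min_image(tg[i, ], pr[j, ], box)
    s[as.character(res_uid[j])] <- s[as.character(res_uid[j])] +
      2 / (1 + exp(scale * r))
  }
  s
}

# single-linkage components via union-find over the full distance matrix
oracle_components <- function(pts, box, cutoff) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (oracle_min_image(pts[i, ], pts[j, ], box) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))   # canonical component ids in first-seen order
}

# a trajectory from explicit coordinate arrays (big box = effectively no PBC)
make_traj <- function(coords, dt = 1, box = c(1e4, 1e4, 1e4),
                      unwrapped = coords, atoms = NULL) {
  trajectory(coords, (seq_len(dim(coords)[1]) - 1) * dt, box,
             unwrapped = unwrapped, atoms = atoms)
}

# straight-line (ballistic) single-particle trajectory x = v t
make_ballistic <- function(v = c(2, -1), n = 50, dt = 1) {
  co <- array(0, c(n, 1, 3))
  t <- (seq_len(n) - 1) * dt
  co[, 1, 1] <- v[1] * t
  co[, 1, 2] <- v[2] * t
  co[, 1, 3] <- 5
  make_traj(co %% 1e4, dt = dt, unwrapped = co,
            atoms = data.frame(atom_name = "GL", res_id = 1,
                               res_name = "TG", mol_id = 1))
}

# minimal one-bead-per-molecule TG selection over all particles
tg_selection <- function(traj) {
  build_selection(list(tg = list(resname = "TG", glycerol_atoms = "GL")),
                  traj$atoms)
}
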