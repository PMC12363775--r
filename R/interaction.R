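#' Coarse-grained mapping rules
#'
#' A mapping is a list of rules, each `list(resname =, bead =, atoms =)`:
#' within every residue instance whose name matches `resname`, the named
#' member atoms are collapsed into one bead placed at their (unweighted by
#' default) centroid. Rules may also be read from a YAML file holding a
#' `rules:` list in the same shape (Martini-style residue -> bead -> atoms
#' table). Within one residue's rule set no atom may belong to two beads.
#'
#' @param rules list of rules, or path to a YAML mapping file.
#' @return object of class `cg_mapping`.
#' @export
cg_mapping <- function(rules) {
  if (is.character(rules) && length(rules) == 1L && file.exists(rules))
    rules <- yaml::read_yaml(rules)$rules
  for (r in rules) {
    if (is.null(r$resname) || is.null(r$bead) || !length(r$atoms))
      stop("each mapping rule needs resname, bead and a non-empty atoms list")
  }
  by_res <- split(rules, vapply(rules, `[[`, "", "resname"))
  for (rn in names(by_res)) {
    atoms <- unlist(lapply(by_res[[rn]], `[[`, "atoms"))
    if (anyDuplicated(atoms))
      stop("atom(s) ", paste(unique(atoms[duplicated(atoms)]),
                             collapse = ", "),
           " mapped to more than one bead in residue ", rn)
  }
  structure(list(rules = rules), class = "cg_mapping")
}

#' Map an all-atom trajectory to coarse-grained beads
#'
#' Applies a [cg_mapping()] residue by residue: each bead's coordinate is
#' the unweighted centroid of its member atoms, per frame (mass weighting
#' optional via `weights`). Residues without a matching rule are an error by
#' default (`unmapped = "drop"` silently removes them instead). A missing
#' member atom is an error naming the residue and atom.
#'
#' @param traj an all-atom [trajectory()] with a topology.
#' @param mapping a [cg_mapping()].
#' @param unmapped `"error"` or `"drop"` for residues no rule covers.
#' @param weights optional named numeric vector of per-atom-name masses for
#'   mass-weighted centroids.
#' @return a CG-resolution [trajectory()] whose topology has one row per
#'   bead (`atom_name` = bead name).
#' @export
map_to_cg <- function(traj, mapping, unmapped = c("error", "drop"),
                      weights = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(mapping, "cg_mapping"))
  unmapped <- match.arg(unmapped)
  if (is.null(traj$atoms)) stop("trajectory has no topology table")
  top <- traj$atoms
  rule_res <- vapply(mapping$rules, `[[`, "", "resname")
  beads <- list()
  for (u in unique(top$res_uid)) {
    rows <- which(top$res_uid == u)
    rn <- top$res_name[rows[1]]
    rules_u <- mapping$rules[rule_res == rn]
    if (!length(rules_u)) {
      if (unmapped == "error")
        stop("no mapping rule for residue ", rn, " ", top$res_id[rows[1]])
      next
    }
    for (r in rules_u) {
      m <- match(r$atoms, top$atom_name[rows])
      if (anyNA(m))
        stop("residue ", rn, " ", top$res_id[rows[1]], ": missing atom(s) ",
             paste(r$atoms[is.na(m)], collapse = ", "))
      beads[[length(beads) + 1L]] <- list(
        idx = rows[m], bead = r$bead, res_id = top$res_id[rows[1]],
        res_name = rn, mol_id = top$mol_id[rows[1]], res_uid = u)
    }
  }
  if (!length(beads)) stop("mapping produced no beads")
  nb <- length(beads)
  co <- array(NA_real_, c(traj$n_frames, nb, 3))
  for (b in seq_len(nb)) {
    idx <- beads[[b]]$idx
    w <- if (is.null(weights)) rep(1, length(idx)) else {
      wv <- weights[top$atom_name[idx]]
      if (anyNA(wv)) stop("weights missing for atom(s) ",
                          paste(top$atom_name[idx][is.na(wv)], collapse = ", "))
      wv
    }
    w <- w / sum(w)
    sub <- traj$coords[, idx, , drop = FALSE]
    for (k in 1:3)
      co[, b, k] <- as.vector(matrix(sub[, , k], ncol = length(idx)) %*% w)
  }
  atoms <- data.frame(
    atom_name = vapply(beads, `[[`, "", "bead"),
    res_id = vapply(beads, `[[`, 0, "res_id"),
    res_name = vapply(beads, `[[`, "", "res_name"),
    mol_id = vapply(beads, `[[`, 0, "mol_id"),
    res_uid = vapply(beads, `[[`, 0, "res_uid"))
  trajectory(co, traj$times, traj$box, atoms = atoms)
}

#' Per-residue TG-protein interaction score
#'
#' For every protein residue, sums the logistic kernel
#' `2 / (1 + exp(kernel_scale * r))` over all (TG bead, residue bead)
#' minimum-image distance pairs, per frame; the per-frame score is averaged
#' over time by default (`average = FALSE` returns the per-frame sum
#' total). The kernel equals 1 at contact (`r = 0`) and decays on a
#' `1/kernel_scale` length scale; the default 0.5 (per Angstrom) gives a
#' ~9 Angstrom decay, i.e. CG bead-contact range. The distance unit entering
#' the kernel is the package-internal Angstrom and is echoed in the result,
#' because rescaling the unit changes scores by orders of magnitude.
#'
#' An optional distance cap `cutoff` skips pairs beyond it; the neglected
#' per-pair tail is bounded by `2 * exp(-kernel_scale * cutoff)`, recorded
#' in the result. The default 30 Angstrom keeps that bound below 1e-6.
#'
#' @param traj a CG-resolution [trajectory()] (use [map_to_cg()] first for
#'   all-atom input).
#' @param sel a [build_selection()] result.
#' @param kernel_scale logistic decay rate (per Angstrom).
#' @param cutoff distance cap (Angstrom) or `NULL` for exact all-pairs.
#' @param average `TRUE` for time averages, `FALSE` for sums over frames.
#' @return `data.frame` of class `interaction_profile` with one row per
#'   protein residue instance: `res_uid`, `res_id`, `res_name`, `n_beads`,
#'   `score`.
#' @export
interaction_score <- function(traj, sel, kernel_scale = 0.5, cutoff = 30,
                              average = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(sel$tg_beads)) stop("TG bead group is empty")
  if (!length(sel$protein)) stop("protein group is empty")
  p_idx <- sel$protein
  res_uid <- sel$res_uid[p_idx]
  uids <- unique(res_uid)
  acc <- numeric(length(uids))
  for (f in seq_len(traj$n_frames)) {
    tg <- matrix(traj$coords[f, sel$tg_beads, ], ncol = 3)
    pr <- matrix(traj$coords[f, p_idx, ], ncol = 3)
    dm <- .min_image_dist_matrix(tg, pr, traj$box[f, ])
    kern <- 2 / (1 + exp(kernel_scale * dm))
    if (!is.null(cutoff)) kern[dm > cutoff] <- 0
    per_bead <- colSums(kern)
    acc <- acc + as.vector(tapply(per_bead, factor(res_uid, levels = uids),
                                  sum))
  }
  if (average) acc <- acc / traj$n_frames
  first <- match(uids, res_uid)
  structure(data.frame(
    res_uid = uids,
    res_id = sel$res_id[p_idx][first],
    res_name = sel$res_name[p_idx][first],
    n_beads = as.vector(table(factor(res_uid, levels = uids))),
    score = acc),
    class = c("interaction_profile", "data.frame"),
    kernel_scale = kernel_scale, cutoff = cutoff,
    tail_bound = if (is.null(cutoff)) 0 else 2 * exp(-kernel_scale * cutoff),
    length_unit = "angstrom", averaged = average,
    n_frames = traj$n_frames)
}

#' Rank residues by interaction score and flag residues of interest
#'
#' Aggregates the profile by residue label (`RESNAME`+`res_id`, averaging
#' over symmetry copies such as the protomers of a ring), ranks by
#' descending score, and flags whether each residue of interest falls in the
#' top quantile.
#'
#' @param profile an [interaction_score()] result.
#' @param residues_of_interest character vector like `c("PHE57", "SER61")`
#'   (matched case-insensitively); may be empty.
#' @param top_frac quantile defining a "peak" (default top 25%).
#' @return `data.frame` ranked by score with columns `residue`, `score`,
#'   `rank`, `in_top`; `attr(, "interest")` summarises the flagged
#'   residues. Naming an absent residue is an error.
#' @export
profile_peaks <- function(profile, residues_of_interest = character(),
                          top_frac = 0.25) {
  lab <- toupper(paste0(profile$res_name, profile$res_id))
  agg <- stats::aggregate(list(score = profile$score), list(residue = lab),
                          mean)
  agg <- agg[order(-agg$score, agg$residue), ]
  agg$rank <- seq_len(nrow(agg))
  n_top <- max(1L, ceiling(top_frac * nrow(agg)))
  agg$in_top <- agg$rank <= n_top
  rownames(agg) <- NULL
  if (length(residues_of_interest)) {
    roi <- toupper(residues_of_interest)
    miss <- setdiff(roi, agg$residue)
    if (length(miss))
      stop("residue(s) not in profile: ", paste(miss, collapse = ", "))
    attr(agg, "interest") <- agg[match(roi, agg$residue), ]
  }
  attr(agg, "top_frac") <- top_frac
  agg
}
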