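#' Build a selection set from a topology
#'
#' Resolves the named particle groups every analysis module consumes: the TG
#' beads, the TG central-glycerol beads (the tracked moiety in all
#' per-molecule analyses), the protein beads, and any user-defined residue
#' groups (e.g. individual serines for per-residue binding series).
#'
#' `spec` is a list, or a path to a YAML file holding one, with fields:
#' \describe{
#'   \item{tg}{`resname` (one or more residue names counted as TG) and
#'     optionally `glycerol_atoms` (atom names of the central glycerol bead;
#'     defaults to all TG atoms whose name starts with "GL" or equals "Na",
#'     the glycerol-linker bead of the 6-bead-per-chain CG TG model).}
#'   \item{protein}{optional; `residues` (IDs) and/or `resnames` restricting
#'     the protein group. Default: every non-TG particle.}
#'   \item{groups}{named list; each entry has `residues`, given either as
#'     numeric IDs or as strings like `"SER61"` (residue name + ID, matched
#'     case-insensitively).}
#' }
#' Unresolvable residues are a hard error listing the offending names; an
#' empty group for a required role is likewise an error.
#'
#' @param spec selection specification (list or YAML path).
#' @param topology a topology `data.frame` (from a [trajectory()]) or a
#'   trajectory object.
#' @return an object of class `selection_set`: particle index vectors for
#'   roles `tg_beads`, `tg_glycerol`, `protein`; named `groups`; and the
#'   per-particle `res_id`, `res_name`, `res_uid`, `mol_id` vectors.
#' @export
build_selection <- function(spec, topology) {
  if (is.character(spec) && length(spec) == 1L && file.exists(spec))
    spec <- yaml::read_yaml(spec)
  if (inherits(topology, "trajectory")) topology <- topology$atoms
  if (is.null(topology)) stop("no topology table available")
  top <- as.data.frame(topology)
  if (is.null(top$res_uid)) {
    key <- paste(top$mol_id, top$res_id, top$res_name)
    top$res_uid <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  }
  tg_res <- spec$tg$resname
  if (is.null(tg_res)) stop("selection spec must name tg$resname")
  tg_beads <- which(top$res_name %in% tg_res)
  if (!length(tg_beads))
    stop("TG group is empty: no particles with res_name in {",
         paste(tg_res, collapse = ", "), "}")
  gl_names <- spec$tg$glycerol_atoms
  tg_glycerol <- if (is.null(gl_names)) {
    tg_beads[grepl("^GL", top$atom_name[tg_beads]) |
               top$atom_name[tg_beads] == "Na"]
  } else tg_beads[top$atom_name[tg_beads] %in% gl_names]
  if (!length(tg_glycerol))
    stop("TG glycerol group is empty",
         if (!is.null(gl_names)) paste0(" (atoms ",
                                        paste(gl_names, collapse = ", "),
                                        " not found in TG)") else "")
  protein <- setdiff(seq_len(nrow(top)), tg_beads)
  if (!is.null(spec$protein$resnames))
    protein <- protein[top$res_name[protein] %in% spec$protein$resnames]
  if (!is.null(spec$protein$residues))
    protein <- protein[top$res_id[protein] %in% spec$protein$residues]

  resolve_residues <- function(entries, group_name) {
    idx <- integer(0); missing <- character(0)
    for (e in entries) {
      if (is.numeric(e) || grepl("^[0-9]+$", e)) {
        hit <- which(top$res_id == as.integer(e))
        lab <- as.character(e)
      } else {
        m <- regmatches(e, regexec("^([A-Za-z]+)([0-9]+)$", e))[[1]]
        if (length(m) != 3) stop("cannot parse residue '", e,
                                 "' in group '", group_name, "'")
        hit <- which(toupper(top$res_name) == toupper(m[2]) &
                       top$res_id == as.integer(m[3]))
        lab <- e
      }
      if (!length(hit)) missing <- c(missing, lab) else idx <- c(idx, hit)
    }
    list(idx = sort(unique(idx)), missing = missing)
  }

  groups <- list(); unresolved <- character(0)
  for (g in names(spec$groups)) {
    r <- resolve_residues(spec$groups[[g]]$residues, g)
    if (length(r$missing))
      unresolved <- c(unresolved, paste0(g, ": ",
                                         paste(r$missing, collapse = ", ")))
    groups[[g]] <- r$idx
  }
  if (length(unresolved))
    stop("unresolved residues in selection spec -- ",
         paste(unresolved, collapse = "; "))
  structure(list(
    tg_beads = tg_beads, tg_glycerol = tg_glycerol, protein = protein,
    groups = groups,
    res_id = top$res_id, res_name = top$res_name,
    res_uid = top$res_uid, mol_id = top$mol_id
  ), class = "selection_set")
}

#' @export
print.selection_set <- function(x, ...) {
  cat("<selection_set> tg_beads:", length(x$tg_beads),
      " tg_glycerol:", length(x$tg_glycerol),
      " protein:", length(x$protein), "\n")
  if (length(x$groups))
    cat("  groups:", paste(sprintf("%s[%d]", names(x$groups),
                                   lengths(x$groups)), collapse = " "), "\n")
  invisible(x)
}

# molecule IDs of the TG molecules, in sorted order
.tg_molecules <- function(sel) sort(unique(sel$mol_id[sel$tg_glycerol]))

# [n_frames, n_tg_mol, 2|3] array of per-molecule glycerol-bead centroids
.glycerol_centroids <- function(traj, sel, dims = 3L, unwrapped = FALSE) {
  mols <- .tg_molecules(sel)
  src <- if (unwrapped) traj$unwrapped else traj$coords
  if (is.null(src)) stop("unwrapped coordinates requested but absent; ",
                         "call unwrap() first")
  out <- array(NA_real_, c(traj$n_frames, length(mols), dims))
  mol_of <- sel$mol_id[sel$tg_glycerol]
  if (!anyDuplicated(mol_of)) {       # one glycerol bead per molecule
    idx <- sel$tg_glycerol[match(mols, mol_of)]
    out[] <- src[, idx, seq_len(dims), drop = FALSE]
    dimnames(out) <- list(NULL, as.character(mols), NULL)
    return(out)
  }
  for (m in seq_along(mols)) {
    idx <- sel$tg_glycerol[sel$mol_id[sel$tg_glycerol] == mols[m]]
    sub <- src[, idx, seq_len(dims), drop = FALSE]
    out[, m, ] <- apply(sub, c(1, 3), mean)
  }
  dimnames(out) <- list(NULL, as.character(mols), NULL)
  out
}
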