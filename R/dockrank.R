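# Docking post-processing: pose clustering, representative ("hit")
# selection, compound ranking, pocket residue enumeration and grid boxes.

pose_rmsd <- function(a, b) {
  # poses share the receptor coordinate frame: plain coordinate RMSD,
  # no superposition, no symmetry correction
  if (nrow(a$xyz) != nrow(b$xyz))
    stop("pose mismatch: poses have different atom counts")
  rmsd_xyz(a$xyz, b$xyz)
}

#' Cluster docking poses by coordinate RMSD
#'
#' Greedy energy-ordered clustering: poses are visited by ascending docking
#' score; a pose joins the first existing cluster whose representative
#' (lowest-energy member, i.e. its seed) lies within `rmsd_cutoff_A`,
#' otherwise it seeds a new cluster. Pose-pose RMSD is computed without
#' superposition since all poses are expressed in the receptor frame.
#' Clusters are returned by descending size, ties broken by better (lower)
#' best energy.
#'
#' @param poses list of `gtusc_pose` objects sharing atom count and order.
#' @param rmsd_cutoff_A join cutoff in Angstrom (default 2.0, the common
#'   docking-community choice; record the value used in pipeline runs).
#' @return list of `gtusc_pose_cluster` objects, each with `members`,
#'   `size`, `best_energy` and `representative` (its lowest-energy member).
#' @export
cluster_poses <- function(poses, rmsd_cutoff_A = 2.0) {
  if (!length(poses)) stop("empty input: no poses")
  stopifnot(rmsd_cutoff_A > 0)
  nat <- vapply(poses, function(p) nrow(p$xyz), integer(1))
  if (length(unique(nat)) != 1L)
    stop("pose mismatch: poses have different atom counts")
  ord <- order(vapply(poses, `[[`, numeric(1), "energy"))
  reps <- list(); members <- list()
  for (k in ord) {
    p <- poses[[k]]
    placed <- FALSE
    for (cl in seq_along(reps)) {
      if (pose_rmsd(p, reps[[cl]]) <= rmsd_cutoff_A) {
        members[[cl]] <- c(members[[cl]], list(p))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, list(p))       # seed = lowest-energy member
      members <- c(members, list(list(p)))
    }
  }
  clusters <- lapply(seq_along(reps), function(cl) {
    en <- vapply(members[[cl]], `[[`, numeric(1), "energy")
    structure(list(members = members[[cl]], size = length(members[[cl]]),
                   best_energy = min(en), representative = reps[[cl]]),
              class = "gtusc_pose_cluster")
  })
  sz <- vapply(clusters, `[[`, integer(1), "size")
  be <- vapply(clusters, `[[`, numeric(1), "best_energy")
  clusters[order(-sz, be)]
}

#' Select the representative hit pose
#'
#' The lowest-energy conformation from the largest cluster. Ties on size
#' are broken by lower best energy, then lexicographically by compound id
#' and model index so the choice is deterministic.
#'
#' @param clusters list of pose clusters from [cluster_poses()].
#' @return A `gtusc_pose`.
#' @export
select_hit <- function(clusters) {
  if (!length(clusters)) stop("empty input: no clusters")
  sz <- vapply(clusters, `[[`, integer(1), "size")
  be <- vapply(clusters, `[[`, numeric(1), "best_energy")
  cid <- vapply(clusters, function(cl) cl$representative$compound_id,
                character(1))
  mid <- vapply(clusters, function(cl) cl$representative$model_index,
                integer(1))
  best <- order(-sz, be, cid, mid)[1L]
  clusters[[best]]$representative
}

#' Rank compounds by largest-cluster size then energy
#'
#' The preferred ligands are those whose docking runs give clusters with a
#' maximum number of conformations and minimum energy: compounds are
#' ordered by largest cluster size (descending), then by that cluster's
#' best energy (ascending), then by compound id for determinism. Ranks are
#' assigned 1..n.
#'
#' @param per_compound named list: compound id -> list of pose clusters
#'   (each from [cluster_poses()], already size-sorted).
#' @return data.frame `compound_id`, `largest_cluster_size`, `best_energy`,
#'   `rank`, in rank order.
#' @export
rank_compounds <- function(per_compound) {
  if (!length(per_compound)) stop("empty input: no compounds")
  rows <- lapply(names(per_compound), function(id) {
    cl <- per_compound[[id]]
    if (!length(cl)) stop("compound ", id, " has no clusters")
    top <- cl[[1L]]    # clusters are sorted size-desc, energy tie-break
    data.frame(compound_id = id, largest_cluster_size = top$size,
               best_energy = top$best_energy, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$largest_cluster_size, out$best_energy,
                   out$compound_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enumerate binding-pocket residues
#'
#' Residues of the receptor with at least one atom within `cutoff_A` of at
#' least one atom of at least one pose; this is the footprint the docked
#' ensemble carves out at the interface.
#'
#' @param receptor a `gtusc_frame` in the same coordinate frame as the poses.
#' @param poses list of `gtusc_pose` objects (possibly empty: empty result,
#'   not an error).
#' @param cutoff_A distance cutoff in Angstrom (default 4.0).
#' @return list with `residues` (data.frame `chain`, `resno`, `resname`) and
#'   `ranges` (named character: per-chain sorted range strings such as
#'   `"515-536, 617-632"`).
#' @export
pocket_residues <- function(receptor, poses, cutoff_A = 4.0) {
  stopifnot(cutoff_A > 0)
  empty <- data.frame(chain = character(0), resno = integer(0),
                      resname = character(0), stringsAsFactors = FALSE)
  if (!length(poses))
    return(list(residues = empty, ranges = character(0)))
  lig <- do.call(rbind, lapply(poses, `[[`, "xyz"))
  rx <- receptor$xyz
  d2 <- outer(rowSums(rx^2), rowSums(lig^2), "+") - 2 * tcrossprod(rx, lig)
  near <- apply(d2 <= cutoff_A^2 + 1e-12, 1L, any)
  a <- receptor$atoms[near, , drop = FALSE]
  if (!nrow(a)) return(list(residues = empty, ranges = character(0)))
  res <- a[!duplicated(a[c("chain", "resno")]), c("chain", "resno", "resname")]
  res <- res[order(res$chain, res$resno), ]
  rownames(res) <- NULL
  ranges <- vapply(split(res$resno, res$chain), format_residue_ranges,
                   character(1))
  list(residues = res, ranges = ranges)
}

#' Collapse residue numbers into range strings
#'
#' `c(515:536, 617:632)` becomes `"515-536, 617-632"`; isolated residues
#' are printed alone (`"337"`).
#'
#' @param resno integer residue numbers (any order, duplicates allowed).
#' @return single character string.
#' @export
format_residue_ranges <- function(resno) {
  resno <- sort(unique(as.integer(resno)))
  if (!length(resno)) return("")
  brk <- c(0L, which(diff(resno) > 1L), length(resno))
  parts <- vapply(seq_len(length(brk) - 1L), function(k) {
    seg <- resno[(brk[k] + 1L):brk[k + 1L]]
    if (length(seg) == 1L) as.character(seg)
    else paste0(seg[1L], "-", seg[length(seg)])
  }, character(1))
  paste(parts, collapse = ", ")
}

#' Residue count spanned by range strings
#'
#' Inclusive span arithmetic: `"328-342"` covers 15 residues, `"335-342"`
#' covers 8. Accepts comma-separated multi-range strings and both ASCII
#' hyphen and en dash.
#'
#' @param spans character vector of range strings.
#' @return integer vector of residue counts.
#' @export
residue_span_length <- function(spans) {
  vapply(spans, function(s) {
    parts <- strsplit(gsub("–", "-", s), ",")[[1L]]
    sum(vapply(trimws(parts), function(p) {
      ends <- as.integer(strsplit(p, "-")[[1L]])
      if (length(ends) == 1L) 1L else ends[2L] - ends[1L] + 1L
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Define a docking grid box
#'
#' Axis-aligned search volume: centre plus per-axis size with fixed grid
#' spacing. The per-axis point count is `floor(size/spacing) + 1`.
#'
#' @param center numeric 3-vector, Angstrom.
#' @param size numeric 3-vector of positive edge lengths, Angstrom.
#' @param spacing_A positive grid spacing (default 1).
#' @return list of class `gtusc_grid_box` with `center`, `size`, `spacing`
#'   and integer `points` per axis.
#' @export
make_grid_box <- function(center, size, spacing_A = 1.0) {
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 3L, length(size) == 3L)
  if (any(size <= 0) || spacing_A <= 0)
    stop("grid box sizes and spacing must be positive")
  structure(list(center = center, size = size, spacing = spacing_A,
                 points = as.integer(floor(size / spacing_A) + 1L)),
            class = "gtusc_grid_box")
}

#' @export
print.gtusc_grid_box <- function(x, ...) {
  cat(sprintf("grid box: center (%.3f, %.3f, %.3f) A, size (%g, %g, %g) A,",
              x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]),
      sprintf("spacing %g A -> %d x %d x %d points\n", x$spacing,
              x$points[1], x$points[2], x$points[3]))
  invisible(x)
}
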