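# Trajectory post-analysis: least-squares superposition, RMSD time series,
# intermolecular contact detection, persistence scoring, residue-pair
# histograms, interface residue extraction and greedy frame clustering.

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

kabsch <- function(mobile, reference) {
  # least-squares rigid fit (rotation + translation, reflection excluded)
  if (nrow(mobile) != nrow(reference))
    stop("selections map to unequal atom counts")
  if (nrow(mobile) < 3L)
    stop("geometry error: superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinear selections leave the rotation about the common axis undefined
  if (qr(A)$rank < 2L || qr(B)$rank < 2L)
    stop("geometry error: degenerate (collinear) atom selection")
  s <- svd(crossprod(A, B))           # t(A) %*% B
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)           # maps centred mobile onto centred ref
  list(rotation = R, center_mobile = cm, center_reference = cr)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2, tr$center_mobile) %*% t(tr$rotation), 2,
        tr$center_reference, "+")
}

#' Superpose one frame onto another
#'
#' Least-squares rigid-body fit (Kabsch): rotation plus translation with
#' reflections excluded. The fit is computed on `selection` and the returned
#' transform can be applied to all atoms.
#'
#' @param mobile,reference `gtusc_frame` objects with identical atom tables.
#' @param selection optional integer or logical index into the atom table;
#'   default all atoms. At least 3 non-collinear atoms are required.
#' @return A list with `rotation` (3x3), `center_mobile`, `center_reference`
#'   (the transform maps `(x - center_mobile) %*% t(rotation) +
#'   center_reference`), `rmsd` (post-fit RMSD over the selection, Angstrom)
#'   and `xyz_fit` (all mobile atoms after the transform).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile$atoms))
  mx <- mobile$xyz[selection, , drop = FALSE]
  rx <- reference$xyz[selection, , drop = FALSE]
  tr <- kabsch(mx, rx)
  fit_sel <- apply_transform(mx, tr)
  list(rotation = tr$rotation, center_mobile = tr$center_mobile,
       center_reference = tr$center_reference,
       rmsd = rmsd_xyz(fit_sel, rx),
       xyz_fit = apply_transform(mobile$xyz, tr))
}

#' Superposition-corrected RMSD time series
#'
#' For every frame, the whole structure is superposed onto the reference
#' frame (all atoms in the fit), correcting for global rotation and
#' translation of the complex; the RMSD of each named atom group is then
#' reported in that common frame without re-fitting per group. This is how
#' per-chain and per-interface deviations are tracked along a simulation
#' while ignoring the tumbling of the whole complex.
#'
#' @param traj a `gtusc_traj`.
#' @param reference_index frame used as reference (default 1).
#' @param groups named list of atom index vectors (integer or logical);
#'   default one group `all` containing every atom.
#' @return data.frame with columns `frame`, then one RMSD column (Angstrom)
#'   per group.
#' @export
rmsd_series <- function(traj, reference_index = 1L, groups = NULL) {
  nf <- n_frames(traj)
  if (reference_index < 1L || reference_index > nf)
    stop("reference index ", reference_index, " out of range 1..", nf)
  na <- nrow(traj$atoms)
  if (is.null(groups)) groups <- list(all = seq_len(na))
  groups <- lapply(groups, function(g) {
    if (is.logical(g)) which(g) else as.integer(g)
  })
  ref <- get_frame(traj, reference_index)
  out <- matrix(NA_real_, nf, length(groups),
                dimnames = list(NULL, names(groups)))
  for (i in seq_len(nf)) {
    sp <- superpose(get_frame(traj, i), ref)
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      out[i, g] <- rmsd_xyz(sp$xyz_fit[idx, , drop = FALSE],
                            ref$xyz[idx, , drop = FALSE])
    }
  }
  data.frame(frame = seq_len(nf), out, check.names = FALSE)
}

#' Select atoms of a frame or trajectory
#'
#' @param x a `gtusc_frame` or `gtusc_traj`.
#' @param chain optional chain id(s) to keep.
#' @param heavy_only drop hydrogens (element `H`)?
#' @return integer vector of atom indices.
#' @export
atom_select <- function(x, chain = NULL, heavy_only = FALSE) {
  a <- x$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (heavy_only) keep <- keep & toupper(a$element) != "H"
  which(keep)
}

#' Intermolecular contacts in one frame
#'
#' All atom pairs with one atom in each chain of `chain_pair` whose Euclidean
#' distance is within `threshold_A` (inclusive). Intramolecular pairs are
#' never reported.
#'
#' @param frame a `gtusc_frame`.
#' @param chain_pair character vector of two chain ids.
#' @param threshold_A distance threshold in Angstrom (default 3.0).
#' @param heavy_only restrict to non-hydrogen atoms (default `FALSE`: the
#'   simulated system is all-atom and contacts are scored at atomic level).
#' @return data.frame of contact events: `chain_i`, `resno_i`, `resname_i`,
#'   `name_i`, `serial_i`, the `_j` counterparts, and `distance_A`.
#' @export
find_contacts <- function(frame, chain_pair, threshold_A = 3.0,
                          heavy_only = FALSE) {
  stopifnot(length(chain_pair) == 2L, threshold_A > 0)
  a <- frame$atoms
  for (ch in chain_pair)
    if (!ch %in% a$chain) stop("unknown chain: ", ch)
  ii <- atom_select(frame, chain_pair[1L], heavy_only)
  jj <- atom_select(frame, chain_pair[2L], heavy_only)
  xi <- frame$xyz[ii, , drop = FALSE]
  xj <- frame$xyz[jj, , drop = FALSE]
  # squared cross-distance matrix
  d2 <- outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * tcrossprod(xi, xj)
  hit <- which(d2 <= threshold_A^2 + 1e-12, arr.ind = TRUE)
  i <- ii[hit[, 1L]]; j <- jj[hit[, 2L]]
  data.frame(chain_i = a$chain[i], resno_i = a$resno[i],
             resname_i = a$resname[i], name_i = a$name[i],
             serial_i = a$serial[i],
             chain_j = a$chain[j], resno_j = a$resno[j],
             resname_j = a$resname[j], name_j = a$name[j],
             serial_j = a$serial[j],
             distance_A = sqrt(pmax(d2[hit], 0)),
             stringsAsFactors = FALSE)
}

#' Default analysis window of a trajectory
#'
#' The first fraction of frames is discarded as equilibration (a 10 ns run
#' of this complex needed about 3 ns to equilibrate, hence the 0.3 default,
#' expressed as a fraction so it scales to trajectories of any length).
#'
#' @param traj a `gtusc_traj`.
#' @param skip_frac fraction of initial frames to skip (default 0.3).
#' @return integer vector of frame indices.
#' @export
analysis_window <- function(traj, skip_frac = 0.3) {
  nf <- n_frames(traj)
  start <- floor(skip_frac * nf) + 1L
  seq.int(start, nf)
}

#' Contact events across an analysis window
#'
#' Runs [find_contacts()] on each window frame and stacks the events with a
#' `frame_index` column; input to [residue_histogram()].
#'
#' @inheritParams find_contacts
#' @param traj a `gtusc_traj`.
#' @param window integer frame indices (default [analysis_window()]).
#' @return data.frame of events with a `frame_index` column.
#' @export
contact_events <- function(traj, chain_pair, threshold_A = 3.0,
                           window = NULL, heavy_only = FALSE) {
  if (is.null(window)) window <- analysis_window(traj)
  if (!length(window)) stop("empty input: empty analysis window")
  ev <- lapply(window, function(i) {
    e <- find_contacts(get_frame(traj, i), chain_pair, threshold_A, heavy_only)
    if (nrow(e)) e$frame_index <- i
    e
  })
  ev <- ev[vapply(ev, nrow, integer(1)) > 0L]
  if (!length(ev)) {
    out <- find_contacts(get_frame(traj, window[1L]), chain_pair, threshold_A,
                         heavy_only)[0, ]
    out$frame_index <- integer(0)
    return(out)
  }
  do.call(rbind, ev)
}

atom_pair_key <- function(ev) {
  paste(ev$chain_i, ev$resno_i, ev$name_i, ev$serial_i,
        ev$chain_j, ev$resno_j, ev$name_j, ev$serial_j, sep = "|")
}

#' Persistent intermolecular contacts
#'
#' For every atom pair (one atom per chain) ever within `threshold_A` inside
#' the analysis window, the fraction of window frames in which the contact
#' is present is computed. Pairs whose fraction strictly exceeds
#' `persistence` are reported as persistent: a pair present in exactly 90%
#' of frames does not pass the default 0.90 cut. Contact identity is the
#' atom pair; residue-level aggregation is done by [residue_histogram()].
#'
#' @inheritParams contact_events
#' @param persistence persistence threshold in \[0,1\] (default 0.90); the
#'   comparison is strict (fraction must exceed it).
#' @return data.frame sorted by (chain, residue, atom) with the event
#'   identity columns plus `n_frames_present`, `n_frames_total` and
#'   `persistence_fraction`.
#' @export
persistent_contacts <- function(traj, chain_pair, threshold_A = 3.0,
                                persistence = 0.90, window = NULL,
                                heavy_only = FALSE) {
  if (is.null(window)) window <- analysis_window(traj)
  if (!length(window)) stop("empty input: empty analysis window")
  ev <- contact_events(traj, chain_pair, threshold_A, window, heavy_only)
  nt <- length(window)
  if (!nrow(ev)) {
    out <- ev[, setdiff(names(ev), c("distance_A", "frame_index"))]
    out$n_frames_present <- integer(0)
    out$n_frames_total <- integer(0)
    out$persistence_fraction <- numeric(0)
    return(out)
  }
  key <- atom_pair_key(ev)
  # a pair can only appear once per frame, so presence = event count
  cnt <- table(key)
  first <- !duplicated(key)
  out <- ev[first, setdiff(names(ev), c("distance_A", "frame_index"))]
  out$n_frames_present <- as.integer(cnt[atom_pair_key(out)])
  out$n_frames_total <- nt
  out$persistence_fraction <- out$n_frames_present / nt
  out <- out[out$persistence_fraction > persistence, , drop = FALSE]
  out <- out[order(out$chain_i, out$resno_i, out$name_i,
                   out$chain_j, out$resno_j, out$name_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Residue-pair contact histogram
#'
#' Aggregates atom-level contact events to residue pairs: for each residue
#' pair, the fraction of analysed frames in which at least one of its atom
#' pairs is in contact. A residue pair can therefore be persistent even when
#' no single atom pair is (alternating atom contacts). Bins whose fraction
#' strictly exceeds `persistence` are flagged persistent (drawn black in the
#' usual histogram rendering).
#'
#' @param events data.frame from [contact_events()] (one chain pair, one
#'   window).
#' @param n_frames number of frames in the analysis window.
#' @param persistence persistence threshold (default 0.90, strict).
#' @return data.frame with residue identity columns for both partners,
#'   `fraction` and logical `persistent`.
#' @export
residue_histogram <- function(events, n_frames, persistence = 0.90) {
  if (n_frames <= 0L) stop("n_frames must be positive")
  if (!nrow(events)) {
    return(data.frame(chain_i = character(0), resno_i = integer(0),
                      resname_i = character(0), chain_j = character(0),
                      resno_j = integer(0), resname_j = character(0),
                      fraction = numeric(0), persistent = logical(0)))
  }
  rkey <- paste(events$chain_i, events$resno_i, events$chain_j,
                events$resno_j, sep = "|")
  fkey <- paste(rkey, events$frame_index, sep = "@")
  # frames with >= 1 atom-pair contact for the residue pair
  present <- tapply(events$frame_index[!duplicated(fkey)],
                    rkey[!duplicated(fkey)], length)
  first <- !duplicated(rkey)
  out <- data.frame(chain_i = events$chain_i[first],
                    resno_i = events$resno_i[first],
                    resname_i = events$resname_i[first],
                    chain_j = events$chain_j[first],
                    resno_j = events$resno_j[first],
                    resname_j = events$resname_j[first],
                    stringsAsFactors = FALSE)
  out$fraction <- as.numeric(present[paste(out$chain_i, out$resno_i,
                                           out$chain_j, out$resno_j,
                                           sep = "|")]) / n_frames
  out$persistent <- out$fraction > persistence
  out <- out[order(out$chain_i, out$resno_i, out$chain_j, out$resno_j), ]
  rownames(out) <- NULL
  out
}

#' Format a residue label
#'
#' Three-letter code in title case followed by the residue number, e.g.
#' `"Glu367"`.
#'
#' @param resname three-letter residue codes.
#' @param resno residue numbers.
#' @return character vector of labels.
#' @export
residue_label <- function(resname, resno) {
  rn <- tolower(resname)
  substr(rn, 1, 1) <- toupper(substr(rn, 1, 1))
  paste0(rn, resno)
}

#' Interface residues from persistent contacts
#'
#' Collapses a persistent atom-contact table to the two per-chain residue
#' lists describing the protein-protein interface: unique residues sorted by
#' residue number, formatted as three-letter-code + number (`Glu367`).
#'
#' @param contacts data.frame from [persistent_contacts()].
#' @return named list, one character vector of residue labels per chain.
#' @export
interface_residues <- function(contacts) {
  if (is.null(contacts) || !nrow(contacts)) return(list())
  side <- function(ch, no, nm) {
    d <- data.frame(chain = ch, resno = no, resname = nm,
                    stringsAsFactors = FALSE)
    d[!duplicated(d[c("chain", "resno")]), ]
  }
  d <- rbind(side(contacts$chain_i, contacts$resno_i, contacts$resname_i),
             side(contacts$chain_j, contacts$resno_j, contacts$resname_j))
  d <- d[!duplicated(d[c("chain", "resno")]), ]
  d <- d[order(d$chain, d$resno), ]
  split(residue_label(d$resname, d$resno), d$chain)
}

#' Greedy centroid clustering of trajectory frames
#'
#' Frames are visited in window order; each is superposed onto the centroid
#' of the first existing cluster whose RMSD to that centroid is within
#' `cutoff_A`, joining it, otherwise it seeds a new cluster. Centroids are
#' the running mean of member coordinates after superposition; the reported
#' dispersion of a cluster is the mean member-to-centroid RMSD. A stable
#' production segment typically collapses into a single cluster whose
#' dispersion summarises its breathing.
#'
#' @param traj a `gtusc_traj`.
#' @param window integer frame indices (default [analysis_window()]).
#' @param cutoff_A RMSD join cutoff in Angstrom (default 1.5).
#' @return A list of class `gtusc_frame_clustering` with `assignments`
#'   (named integer vector, frame index -> cluster id), `centroids` (list of
#'   coordinate matrices) and `dispersion_A` (numeric per cluster).
#' @export
cluster_frames <- function(traj, window = NULL, cutoff_A = 1.5) {
  if (is.null(window)) window <- analysis_window(traj)
  if (!length(window)) stop("empty input: empty frame window")
  stopifnot(cutoff_A > 0)
  centroids <- list()
  members <- list()       # superposed member coordinates per cluster
  assign <- integer(length(window))
  for (w in seq_along(window)) {
    fr <- get_frame(traj, window[w])
    placed <- FALSE
    for (cl in seq_along(centroids)) {
      cen <- make_frame(traj$atoms, centroids[[cl]])
      sp <- superpose(fr, cen)
      if (sp$rmsd <= cutoff_A) {
        members[[cl]] <- c(members[[cl]], list(sp$xyz_fit))
        centroids[[cl]] <- Reduce(`+`, members[[cl]]) / length(members[[cl]])
        assign[w] <- cl
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      centroids <- c(centroids, list(fr$xyz))
      members <- c(members, list(list(fr$xyz)))
      assign[w] <- length(centroids)
    }
  }
  disp <- vapply(seq_along(centroids), function(cl) {
    mean(vapply(members[[cl]], function(m) {
      sp <- superpose(make_frame(traj$atoms, m),
                      make_frame(traj$atoms, centroids[[cl]]))
      sp$rmsd
    }, numeric(1)))
  }, numeric(1))
  structure(list(assignments = setNames(assign, window),
                 centroids = centroids, dispersion_A = disp),
            class = "gtusc_frame_clustering")
}

#' @export
print.gtusc_frame_clustering <- function(x, ...) {
  cat("frame clustering:", length(x$centroids), "cluster(s); sizes",
      paste(tabulate(x$assignments), collapse = ","),
      "; dispersion (A)", paste(sprintf("%.2f", x$dispersion_A),
                                collapse = ","), "\n")
  invisible(x)
}

#' Restrict contacts to donor/acceptor atom pairs
#'
#' Hydrogen-bond-style subset of a contact table: keeps pairs whose atoms
#' are both polar (N, O, S, or hydrogens bonded to them, approximated here
#' by element N/O/S/H with a polar partner). Geometric angle criteria are
#' out of scope; by construction the result is a subset of the input, the
#' property a distance-plus-geometry bond finder satisfies relative to a
#' pure distance scan.
#'
#' @param contacts contact or persistent-contact data.frame.
#' @return the subset of rows with polar elements on both sides.
#' @export
polar_contact_subset <- function(contacts) {
  if (!nrow(contacts)) return(contacts)
  polar <- function(nm) {
    el <- substr(gsub("^[0-9]*", "", nm), 1, 1)
    toupper(el) %in% c("N", "O", "S", "H")
  }
  contacts[polar(contacts$name_i) & polar(contacts$name_j), , drop = FALSE]
}
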