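# Synthetic-data generators. Every pipeline input format can be produced
# with machine-readable ground truth: two-chain trajectories with planted
# contact persistence fractions, docking pose sets with planted spatial
# clusters and energies, fragment property tables with known pass counts,
# and DSF plates with planted melting temperatures. All generators are
# deterministic given a seed and restore the caller's RNG state.

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic two-chain trajectory
#'
#' Chains are rows of minimal three-atom residues spaced 10 Angstrom apart,
#' the two chains separated by 12 Angstrom, so that all inter-chain
#' distances are well above the contact threshold except where contacts are
#' planted. Each planted contact names one residue per chain and a target
#' persistence fraction: in exactly `round(fraction * n_frames)` frames
#' (chosen by seeded permutation, so persistence is insensitive to window
#' placement) the partner atom is placed at `contact_distance_A`, otherwise
#' it stays at least 6 Angstrom away.
#'
#' @param n_frames number of frames.
#' @param n_residues residues per chain (each contributes 3 atoms).
#' @param chains two chain identifiers (default `c("B", "D")`, the
#'   GCP4/gamma-tubulin dimer labelling).
#' @param planted data.frame with columns `res_i`, `res_j` (1-based residue
#'   index within each chain, all distinct per chain), `fraction` in
#'   \[0,1\], `distance_A` (planted contact distance, must sit below the
#'   analysis threshold; default rows may be omitted for a contact-free
#'   trajectory).
#' @param jitter_sigma_A Gaussian coordinate jitter per atom per frame
#'   (default 0.05).
#' @param global_motion apply a rigid per-frame rotation/translation
#'   schedule to the whole system (exercises superposition correction)?
#' @param seed RNG seed.
#' @return list of class `gtusc_traj_spec`.
#' @export
trajectory_spec <- function(n_frames = 200L, n_residues = 6L,
                            chains = c("B", "D"), planted = NULL,
                            jitter_sigma_A = 0.05, global_motion = FALSE,
                            seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(res_i = integer(0), res_j = integer(0),
                          fraction = numeric(0), distance_A = numeric(0))
  stopifnot(length(chains) == 2L, n_frames >= 1L, n_residues >= 1L)
  if (nrow(planted)) {
    if (any(planted$fraction < 0 | planted$fraction > 1))
      stop("planted fractions must lie in [0,1]")
    if (any(planted$distance_A <= 0 | planted$distance_A >= 6))
      stop("infeasible geometry: planted contact distances must lie in (0, 6)")
    if (anyDuplicated(planted$res_i) || anyDuplicated(planted$res_j))
      stop("infeasible geometry: planted contacts must use distinct residues")
    if (any(planted$res_i > n_residues | planted$res_j > n_residues))
      stop("planted residue index exceeds n_residues")
  }
  structure(list(n_frames = as.integer(n_frames),
                 n_residues = as.integer(n_residues), chains = chains,
                 planted = planted, jitter_sigma_A = jitter_sigma_A,
                 global_motion = isTRUE(global_motion),
                 seed = as.integer(seed)),
            class = "gtusc_traj_spec")
}

chain_base_coords <- function(n_residues, z_offset) {
  # residue r: three atoms at x = 10(r-1), y = 0/1/2
  res <- rep(seq_len(n_residues), each = 3L)
  t(vapply(seq_along(res), function(k) {
    c(10 * (res[k] - 1L), (k - 1L) %% 3L, z_offset)
  }, numeric(3)))
}

rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

#' Generate a synthetic two-chain trajectory
#'
#' Realises a [trajectory_spec()]: deterministic per seed, with ground
#' truth listing the frames in which every planted contact is realised.
#' Atoms of a planted pair are placed exactly, so the per-frame contact
#' status is guaranteed regardless of jitter.
#'
#' @param spec a [trajectory_spec()].
#' @return list with `traj` (a `gtusc_traj`), `ground_truth` (data.frame
#'   per planted contact: serials, chains, residues, target and realised
#'   fraction, `n_contact_frames`) and `contact_matrix` (n_frames x
#'   n_contacts logical).
#' @export
gen_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gtusc_traj_spec"))
  with_seed(spec$seed, {
    nr <- spec$n_residues
    nat_chain <- 3L * nr
    aa3 <- c("ALA", "GLY", "SER", "VAL", "LEU", "THR", "ASN", "GLN")
    res_i <- rep(seq_len(nr), each = 3L)
    mk_atoms <- function(chain, serial0) {
      atom_table(serial = serial0 + seq_len(nat_chain),
                 name = rep(c("N", "CA", "O"), nr),
                 element = rep(c("N", "C", "O"), nr),
                 resname = aa3[(res_i - 1L) %% length(aa3) + 1L],
                 resno = res_i, chain = chain)
    }
    atoms <- rbind(mk_atoms(spec$chains[1L], 0L),
                   mk_atoms(spec$chains[2L], nat_chain))
    base <- rbind(chain_base_coords(nr, 0), chain_base_coords(nr, 12))
    pl <- spec$planted
    npl <- nrow(pl)
    # atom index of the contact atom (first atom, "N") of each residue
    idx_i <- (pl$res_i - 1L) * 3L + 1L
    idx_j <- nat_chain + (pl$res_j - 1L) * 3L + 1L
    contact_mat <- matrix(FALSE, spec$n_frames, npl)
    for (c in seq_len(npl)) {
      k <- round(pl$fraction[c] * spec$n_frames)
      if (k > 0L) contact_mat[sample.int(spec$n_frames)[seq_len(k)], c] <- TRUE
    }
    frames <- vector("list", spec$n_frames)
    for (f in seq_len(spec$n_frames)) {
      xyz <- base + matrix(stats::rnorm(length(base), 0, spec$jitter_sigma_A),
                           ncol = 3L)
      for (c in seq_len(npl)) {
        if (contact_mat[f, c]) {
          # -y points away from the residue's other atoms, so only the
          # planted pair falls inside the contact threshold
          xyz[idx_j[c], ] <- xyz[idx_i[c], ] + c(0, -pl$distance_A[c], 0)
        } else {
          xyz[idx_j[c], ] <- base[idx_j[c], ]   # >= 12 A from its partner
        }
      }
      if (spec$global_motion) {
        R <- rot_z((f - 1L) * pi / 90)
        xyz <- xyz %*% t(R) + matrix(rep((f - 1L) * c(0.1, 0.05, 0),
                                         each = nrow(xyz)), ncol = 3L)
      }
      frames[[f]] <- make_frame(atoms, xyz, index = f, time_ps = 5 * (f - 1L))
    }
    traj <- make_trajectory(frames)
    gt <- if (npl) {
      data.frame(serial_i = atoms$serial[idx_i], chain_i = atoms$chain[idx_i],
                 resno_i = atoms$resno[idx_i], name_i = atoms$name[idx_i],
                 serial_j = atoms$serial[idx_j], chain_j = atoms$chain[idx_j],
                 resno_j = atoms$resno[idx_j], name_j = atoms$name[idx_j],
                 target_fraction = pl$fraction,
                 n_contact_frames = colSums(contact_mat),
                 realised_fraction = colSums(contact_mat) / spec$n_frames,
                 distance_A = pl$distance_A, stringsAsFactors = FALSE)
    } else data.frame()
    list(traj = traj, ground_truth = gt, contact_matrix = contact_mat)
  })
}

#' Generate a synthetic docking pose set
#'
#' Poses form spatial families around centres `separation_A` apart along x;
#' within a family every pose is the same rigid ligand translated by a
#' random vector of norm at most `jitter_A`, so intra-family RMSD is at
#' most `2 * jitter_A` and clustering at any cutoff between `2 * jitter_A`
#' and `separation_A - 2 * jitter_A` recovers the planted sizes exactly.
#'
#' @param sizes integer vector of family sizes (first family is the
#'   intended hit cluster).
#' @param energies optional list of energy vectors (kcal/mol), one per
#'   family, lengths matching `sizes`; default assigns the intended hit
#'   family a best score of -11.0 kcal/mol with 0.1 steps, subsequent
#'   families 2 kcal/mol weaker each.
#' @param separation_A centre separation (default 15); must exceed
#'   `2 * jitter_A` plus the clustering cutoff the test intends to use.
#' @param jitter_A maximal per-pose translation (default 0.5).
#' @param n_atoms ligand atom count (default 5).
#' @param compound_id compound name (default `"NM000"`).
#' @param seed RNG seed.
#' @return list with `poses` (list of `gtusc_pose`, shuffled model order
#'   re-indexed 1..n with energies non-decreasing as a docking engine would
#'   emit), `ground_truth` (list: `assignment` per pose, `sizes`,
#'   `hit_model_index`, `hit_energy`).
#' @export
gen_pose_set <- function(sizes, energies = NULL, separation_A = 15,
                         jitter_A = 0.5, n_atoms = 5L,
                         compound_id = "NM000", seed = 1L) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 1L))
  if (separation_A <= 4 * jitter_A)
    stop("infeasible separation: families would overlap")
  if (is.null(energies)) {
    energies <- lapply(seq_along(sizes), function(k) {
      -11.0 + 2 * (k - 1L) + 0.1 * (seq_len(sizes[k]) - 1L)
    })
  }
  stopifnot(length(energies) == length(sizes),
            all(lengths(energies) == sizes))
  with_seed(seed, {
    template <- cbind(seq_len(n_atoms) - 1, 0, 0)   # rigid linear ligand
    atoms <- atom_table(seq_len(n_atoms), rep("C1", n_atoms),
                        rep("C", n_atoms), rep("LIG", n_atoms),
                        rep(1L, n_atoms), rep("L", n_atoms))
    poses <- list(); assign <- integer(0); en_all <- numeric(0)
    for (k in seq_along(sizes)) {
      centre <- c((k - 1L) * separation_A, 0, 30)
      for (m in seq_len(sizes[k])) {
        v <- stats::rnorm(3)
        v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, jitter_A)
        xyz <- sweep(template, 2, centre + v, "+")
        poses <- c(poses, list(structure(
          list(compound_id = compound_id, model_index = 0L,
               energy = energies[[k]][m], atoms = atoms, xyz = xyz),
          class = "gtusc_pose")))
        assign <- c(assign, k)
        en_all <- c(en_all, energies[[k]][m])
      }
    }
    # docking engines emit models sorted by score
    ord <- order(en_all)
    poses <- poses[ord]; assign <- assign[ord]
    for (m in seq_along(poses)) poses[[m]]$model_index <- m
    hit_family <- order(-sizes, vapply(energies, min, numeric(1)))[1L]
    hit_energy <- min(energies[[hit_family]])
    hit_model <- which(assign == hit_family &
                         vapply(poses, `[[`, numeric(1), "energy") ==
                         hit_energy)[1L]
    list(poses = poses,
         ground_truth = list(assignment = assign, sizes = as.integer(sizes),
                             hit_model_index = hit_model,
                             hit_energy = hit_energy))
  })
}

finite_range <- function(r, fallback_span = 100) {
  lo <- r[1L]; hi <- r[2L]
  if (!is.finite(lo) && !is.finite(hi)) return(c(0, fallback_span))
  if (!is.finite(lo)) lo <- hi - fallback_span
  if (!is.finite(hi)) hi <- lo + fallback_span
  c(lo, hi)
}

#' Generate a fragment property table with a planted pass count
#'
#' Exactly `in_range_count` records are drawn inside every filter range;
#' each remaining record violates at least one named range (the violated
#' descriptor is recorded). Row order is a seeded shuffle. Descriptors not
#' constrained by the filter (logS and the count descriptors) are drawn
#' from distributions centred on typical fragment-library averages.
#'
#' @param n total number of records.
#' @param in_range_count how many must pass the filter.
#' @param spec a [filter_spec()] (default [filter_spec()]).
#' @param seed RNG seed.
#' @return list with `table` (data.frame, canonical descriptor columns) and
#'   `ground_truth` (data.frame: `compound_id`, `in_range`,
#'   `violated_property` — `NA` for in-range rows).
#' @export
gen_property_table <- function(n, in_range_count, spec = filter_spec(),
                               seed = 1L) {
  stopifnot(in_range_count <= n, n >= 1L)
  with_seed(seed, {
    int_props <- c("n_atoms", "HAC", "nHA", "NR", "HD", "HA")
    draw_inside <- function(nm, k) {
      r <- finite_range(spec[[nm]])
      v <- stats::runif(k, r[1L], r[2L])
      if (nm %in% int_props) v <- round(v)
      pmin(pmax(v, r[1L]), r[2L])
    }
    tab <- data.frame(compound_id = sprintf("FRAG%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (nm in names(spec)) tab[[nm]] <- draw_inside(nm, n)
    tab$logS <- round(stats::rnorm(n, -3, 1), 2)
    tab$HAC <- pmax(1L, round(stats::rnorm(n, 25, 4)))
    tab$nHA <- pmax(0L, round(stats::rnorm(n, 8, 2)))
    tab$NR <- pmax(0L, round(stats::rnorm(n, 2, 1)))
    tab$HD <- pmax(0L, round(stats::rnorm(n, 2, 1)))
    tab$HA <- pmax(0L, round(stats::rnorm(n, 6, 2)))
    out_rows <- if (n > in_range_count) (in_range_count + 1L):n else integer(0)
    violated <- rep(NA_character_, n)
    for (i in out_rows) {
      nm <- sample(names(spec), 1L)
      r <- spec[[nm]]
      # push outside whichever bound is finite
      v <- if (is.finite(r[2L]) && (stats::runif(1) < 0.5 || !is.finite(r[1L])))
        r[2L] + stats::runif(1, 1, 50)
      else r[1L] - stats::runif(1, 1, 50)
      if (nm %in% int_props) v <- round(v)
      tab[[nm]][i] <- v
      violated[i] <- nm
    }
    ord <- sample.int(n)
    tab <- tab[ord, , drop = FALSE]
    rownames(tab) <- NULL
    gt <- data.frame(compound_id = tab$compound_id,
                     in_range = is.na(violated[ord]),
                     violated_property = violated[ord],
                     stringsAsFactors = FALSE)
    list(table = tab, ground_truth = gt)
  })
}

#' Specify a synthetic DSF plate
#'
#' The default scan emulates a real-time PCR melt protocol: 20 to
#' 89.9 degrees C sampled every 0.3 degrees C (234 inclusive points per
#' well).
#'
#' @param conditions data.frame with columns `name`, `Tm` (degrees C,
#'   inside the scan), `a` (slope, degrees C), `F_min`, `F_max` (AU) and
#'   `n_replicates`.
#' @param noise_sigma_AU Gaussian noise SD added to every reading.
#' @param scan numeric `c(start, end, step)` in degrees C (default
#'   `c(20, 89.9, 0.3)`).
#' @param decay add a linear post-transition decay ramp (SYPRO-Orange-like
#'   dye dissociation) starting 5 slope-widths above Tm? Exercises the fit
#'   window truncation.
#' @param seed RNG seed.
#' @return list of class `gtusc_plate_spec`.
#' @export
plate_spec <- function(conditions, noise_sigma_AU = 90,
                       scan = c(20, 89.9, 0.3), decay = TRUE, seed = 1L) {
  need <- c("name", "Tm", "a", "F_min", "F_max", "n_replicates")
  miss <- setdiff(need, names(conditions))
  if (length(miss))
    stop("conditions missing column(s): ", paste(miss, collapse = ", "))
  if (any(conditions$Tm <= scan[1L] | conditions$Tm >= scan[2L]))
    stop("planted Tm outside the scan range")
  structure(list(conditions = conditions, noise_sigma_AU = noise_sigma_AU,
                 scan = scan, decay = isTRUE(decay), seed = as.integer(seed)),
            class = "gtusc_plate_spec")
}

scan_temperatures <- function(scan) {
  n_pts <- floor((scan[2L] - scan[1L]) / scan[3L] + 1e-9) + 1L
  scan[1L] + scan[3L] * (seq_len(n_pts) - 1L)
}

#' Generate a synthetic DSF plate
#'
#' Boltzmann curves with planted parameters, an optional linear post-peak
#' decay segment, and per-seed Gaussian noise, emitted in the long plate
#' CSV layout the fitting stage reads.
#'
#' @param spec a [plate_spec()].
#' @return list with `plate` (data.frame `well`, `condition`,
#'   `temperature_C`, `fluorescence_AU`) and `ground_truth` (data.frame
#'   `condition`, `Tm`, `a`, `F_min`, `F_max`).
#' @export
gen_plate <- function(spec) {
  stopifnot(inherits(spec, "gtusc_plate_spec"))
  with_seed(spec$seed, {
    temps <- scan_temperatures(spec$scan)
    cond <- spec$conditions
    rows <- list()
    widx <- 0L
    for (i in seq_len(nrow(cond))) {
      for (r in seq_len(cond$n_replicates[i])) {
        widx <- widx + 1L
        well <- sprintf("%s%02d", LETTERS[(widx - 1L) %/% 12L + 1L],
                        (widx - 1L) %% 12L + 1L)
        f <- boltzmann(temps, cond$F_min[i], cond$F_max[i], cond$Tm[i],
                       cond$a[i])
        if (spec$decay) {
          t_peak <- cond$Tm[i] + 5 * cond$a[i]
          post <- temps > t_peak
          if (any(post)) {
            f_peak <- boltzmann(t_peak, cond$F_min[i], cond$F_max[i],
                                cond$Tm[i], cond$a[i])
            f[post] <- f_peak -
              0.02 * (cond$F_max[i] - cond$F_min[i]) * (temps[post] - t_peak)
          }
        }
        if (spec$noise_sigma_AU > 0)
          f <- f + stats::rnorm(length(f), 0, spec$noise_sigma_AU)
        rows[[widx]] <- data.frame(well = well, condition = cond$name[i],
                                   temperature_C = temps,
                                   fluorescence_AU = f,
                                   stringsAsFactors = FALSE)
      }
    }
    list(plate = do.call(rbind, rows),
         ground_truth = cond[c("name", "Tm", "a", "F_min", "F_max")])
  })
}
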