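test_that("superposition removes rigid motion and rejects degenerate selections", {
  set.seed(21)
  atoms <- atom_table(1:6, rep("CA", 6), rep("C", 6), rep("GLY", 6), 1:6, "A")
  xyz <- matrix(runif(18, 0, 10), ncol = 3)
  f1 <- make_frame(atoms, xyz)
  expect_equal(superpose(f1, f1)$rmsd, 0, tolerance = 1e-12)

  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  f2 <- make_frame(atoms, xyz %*% t(R) +
                     matrix(rep(c(1, 2, 3), each = 6), ncol = 3))
  sp <- superpose(f2, f1)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$xyz_fit, f1$xyz, tolerance = 1e-9)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)

  a2 <- atom_table(1:2, c("CA", "CA"), c("C", "C"), c("GLY", "GLY"), 1:2, "A")
  expect_error(superpose(make_frame(a2, xyz[1:2, ]),
                         make_frame(a2, xyz[3:4, ])), "3 atoms")
  a3 <- atom_table(1:3, rep("CA", 3), rep("C", 3), rep("GLY", 3), 1:3, "A")
  line <- cbind(0:2, 0, 0)
  expect_error(superpose(make_frame(a3, line), make_frame(a3, line + 1)),
               "collinear")
})

test_that("Kabsch RMSD matches a brute-force rotation search", {
  set.seed(31)
  atoms <- atom_table(1:4, rep("CA", 4), rep("C", 4), rep("GLY", 4), 1:4, "A")
  for (rep in 1:5) {
    a <- matrix(rnorm(12, sd = 3), ncol = 3)
    b <- matrix(rnorm(12, sd = 3), ncol = 3)
    sp <- superpose(make_frame(atoms, a), make_frame(atoms, b))
    expect_equal(sp$rmsd, brute_min_rmsd(a, b), tolerance = 1e-6)
  }
})

test_that("Kabsch agrees with an established structural-fitting routine", {
  skip_if_not_installed("bio3d")
  set.seed(32)
  a <- matrix(rnorm(30, sd = 3), ncol = 3)
  b <- matrix(rnorm(30, sd = 3), ncol = 3)
  atoms <- atom_table(1:10, rep("CA", 10), rep("C", 10), rep("GLY", 10),
                      1:10, "A")
  sp <- superpose(make_frame(atoms, a), make_frame(atoms, b))
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(b)), mobile = as.vector(t(a)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(sp$rmsd,
               sqrt(mean(colSums(matrix((fitted - as.vector(t(b)))^2,
                                        nrow = 3)))),
               tolerance = 1e-8)
})

test_that("rmsd_series is zero for rigid motion and composes frame-by-frame", {
  rigid <- gen_trajectory(trajectory_spec(n_frames = 6L, n_residues = 4L,
                                          jitter_sigma_A = 0,
                                          global_motion = TRUE, seed = 4L))
  rs <- rmsd_series(rigid$traj)
  expect_true(all(rs$all < 1e-9))

  g <- gen_trajectory(trajectory_spec(n_frames = 5L, n_residues = 4L,
                                      jitter_sigma_A = 0.3, seed = 8L))
  groups <- list(B = atom_select(g$traj, "B"), D = atom_select(g$traj, "D"))
  rs <- rmsd_series(g$traj, 1L, groups)
  expect_equal(rs$B[1], 0, tolerance = 1e-12)
  ref <- get_frame(g$traj, 1L)
  for (i in 2:5) {   # whole-complex fit, then per-group RMSD without refit
    sp <- superpose(get_frame(g$traj, i), ref)
    for (grp in names(groups)) {
      idx <- groups[[grp]]
      expect_equal(rs[[grp]][i],
                   sqrt(mean(rowSums((sp$xyz_fit[idx, ] - ref$xyz[idx, ])^2))),
                   tolerance = 1e-12)
    }
  }
  expect_error(rmsd_series(g$traj, 99L), "out of range")
})

test_that("RMSD series is invariant under a rigid transform of the whole trajectory", {
  g <- gen_trajectory(trajectory_spec(n_frames = 4L, n_residues = 4L,
                                      jitter_sigma_A = 0.3, seed = 12L))
  rs1 <- rmsd_series(g$traj)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  frames <- lapply(seq_len(n_frames(g$traj)), function(i) {
    f <- get_frame(g$traj, i)
    make_frame(f$atoms, f$xyz %*% t(R) +
                 matrix(rep(c(5, -2, 7), each = nrow(f$xyz)), ncol = 3),
               index = i)
  })
  rs2 <- rmsd_series(make_trajectory(frames))
  expect_equal(rs2$all, rs1$all, tolerance = 1e-9)
})

test_that("find_contacts keeps only intermolecular pairs within the threshold", {
  atoms <- atom_table(1:4, rep("CA", 4), rep("C", 4), rep("GLY", 4),
                      c(1L, 2L, 1L, 2L), c("A", "A", "B", "B"))
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1),    # A atoms 1 apart (intramolecular)
               c(0, -2.9, 0), c(50, 0, 0))
  fr <- make_frame(atoms, xyz)
  ev <- find_contacts(fr, c("A", "B"), 3.0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$serial_i, 1L)
  expect_equal(ev$serial_j, 3L)
  expect_equal(ev$distance_A, 2.9, tolerance = 1e-12)
  expect_error(find_contacts(fr, c("A", "Z"), 3.0), "unknown chain")
})

test_that("find_contacts equals the all-pairs brute-force scan on random frames", {
  set.seed(41)
  for (rep in 1:25) {
    fr <- random_two_chain_frame(sample(10:60, 1L))
    thr <- runif(1, 2, 4)
    ev <- find_contacts(fr, c("A", "B"), thr)
    expect_identical(contact_pairs_of(ev),
                     brute_contact_pairs(fr, c("A", "B"), thr))
  }
})

test_that("raising the distance threshold never shrinks a frame's contact set", {
  set.seed(43)
  fr <- random_two_chain_frame(50L)
  prev <- character(0)
  for (thr in c(2, 3, 4, 5)) {
    cur <- contact_pairs_of(find_contacts(fr, c("A", "B"), thr))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("persistence uses a strict cut: exactly 90% presence is not persistent", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 100L, n_residues = 6L,
    planted = data.frame(res_i = 1:4, res_j = 1:4,
                         fraction = c(0.89, 0.90, 0.95, 1.0),
                         distance_A = 2.5),
    seed = 17L))
  pc <- persistent_contacts(g$traj, c("B", "D"), threshold_A = 3.0,
                            persistence = 0.90, window = seq_len(100L))
  expect_equal(sort(pc$persistence_fraction), c(0.95, 1.0))
  expect_equal(sort(pc$resno_i), 3:4)
})

test_that("persistent fractions match frame-by-frame counting and planted truth", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 200L, n_residues = 6L,
    planted = data.frame(res_i = 1:4, res_j = 1:4,
                         fraction = c(1.0, 0.95, 0.60, 0.10),
                         distance_A = 2.5),
    seed = 23L))
  win <- seq_len(200L)
  pc <- persistent_contacts(g$traj, c("B", "D"), 3.0, 0.90, window = win)
  expect_equal(sort(pc$persistence_fraction), c(0.95, 1.0))
  # frame-counting oracle over every pair ever seen
  counts <- new.env()
  for (i in win) {
    ev <- find_contacts(get_frame(g$traj, i), c("B", "D"), 3.0)
    for (k in paste(ev$serial_i, ev$serial_j)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  for (r in seq_len(nrow(pc))) {
    k <- paste(pc$serial_i[r], pc$serial_j[r])
    expect_equal(pc$n_frames_present[r], counts[[k]])
  }
  oracle_persistent <- Filter(function(k) counts[[k]] / 200 > 0.9,
                              ls(counts))
  expect_setequal(paste(pc$serial_i, pc$serial_j), oracle_persistent)
})

test_that("persistent contacts are a subset of all window contacts, monotone in persistence", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 60L, n_residues = 5L,
    planted = data.frame(res_i = 1:3, res_j = 1:3,
                         fraction = c(0.95, 0.7, 0.5), distance_A = 2.5),
    seed = 29L))
  win <- seq_len(60L)
  all_ev <- contact_events(g$traj, c("B", "D"), 3.0, window = win)
  all_keys <- unique(paste(all_ev$serial_i, all_ev$serial_j))
  prev_n <- Inf
  for (p in c(0.3, 0.6, 0.9)) {
    pc <- persistent_contacts(g$traj, c("B", "D"), 3.0, p, window = win)
    expect_true(all(paste(pc$serial_i, pc$serial_j) %in% all_keys))
    expect_lte(nrow(pc), prev_n)
    prev_n <- nrow(pc)
  }
  expect_error(persistent_contacts(g$traj, c("B", "D"), window = integer(0)),
               "empty")
})

test_that("residue histogram is the union over atom pairs, bounded below by each", {
  ev <- data.frame(
    chain_i = "B", resno_i = 1L, resname_i = "ALA",
    name_i = c(rep("N", 5), rep("CA", 5)), serial_i = c(rep(1L, 5), rep(2L, 5)),
    chain_j = "D", resno_j = 1L, resname_j = "GLY",
    name_j = "N", serial_j = 10L,
    distance_A = 2.0, frame_index = c(1:5, 6:10), stringsAsFactors = FALSE)
  h <- residue_histogram(ev, n_frames = 10L, persistence = 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$fraction, 1.0)   # atom pairs each 0.5, union 1.0
  expect_true(h$persistent)

  h2 <- residue_histogram(ev[1:5, ], n_frames = 10L)
  expect_equal(h2$fraction, 0.5)
  expect_false(h2$persistent)

  empty <- residue_histogram(ev[0, ], n_frames = 10L)
  expect_equal(nrow(empty), 0L)
  expect_error(residue_histogram(ev, n_frames = 0L), "positive")
})

test_that("residue-pair fractions dominate atom-pair fractions on generated data", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 80L, n_residues = 5L,
    planted = data.frame(res_i = 1:3, res_j = 1:3,
                         fraction = c(0.95, 0.55, 0.25), distance_A = 2.5),
    seed = 37L))
  win <- seq_len(80L)
  ev <- contact_events(g$traj, c("B", "D"), 3.0, window = win)
  h <- residue_histogram(ev, 80L)
  ap_key <- paste(ev$chain_i, ev$resno_i, ev$chain_j, ev$resno_j)
  ap_frac <- tapply(ev$frame_index,
                    paste(ap_key, ev$serial_i, ev$serial_j),
                    function(x) length(unique(x))) / 80
  for (r in seq_len(nrow(h))) {
    key <- paste(h$chain_i[r], h$resno_i[r], h$chain_j[r], h$resno_j[r])
    sub <- ap_frac[grepl(key, names(ap_frac), fixed = TRUE)]
    expect_gte(h$fraction[r], max(sub))
  }
})

test_that("interface residue lists reproduce the published dimer-1 interface", {
  res <- interface_residues(paper_dimer1_contacts())
  expect_equal(length(res$B), 14L)
  expect_equal(res$B[1], "Glu367")
  expect_equal(res$B[14], "Ser538")
  expect_equal(length(res$D), 17L)
  expect_equal(res$D[1], "Arg2")
  expect_equal(res$D[17], "Trp445")
  expect_equal(interface_residues(NULL), list())
})

test_that("interface residues recover the generator's planted interface", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 100L, n_residues = 6L,
    planted = data.frame(res_i = c(1L, 3L, 5L), res_j = c(2L, 4L, 6L),
                         fraction = c(1, 0.97, 0.2), distance_A = 2.5),
    seed = 41L))
  pc <- persistent_contacts(g$traj, c("B", "D"), window = seq_len(100L))
  res <- interface_residues(pc)
  expect_equal(res$B, c("Ala1", "Ser3"))
  expect_equal(res$D, c("Gly2", "Val4"))
})

test_that("polar-restricted contacts are a subset of the full persistent set", {
  g <- gen_trajectory(trajectory_spec(
    n_frames = 40L, n_residues = 5L,
    planted = data.frame(res_i = 1:2, res_j = 1:2, fraction = c(1, 0.95),
                         distance_A = 2.5),
    seed = 43L))
  pc <- persistent_contacts(g$traj, c("B", "D"), window = seq_len(40L))
  sub <- polar_contact_subset(pc)
  expect_lte(nrow(sub), nrow(pc))
  full_keys <- paste(pc$serial_i, pc$serial_j)
  expect_true(all(paste(sub$serial_i, sub$serial_j) %in% full_keys))
})

test_that("frame clustering collapses identical frames and splits planted families", {
  atoms <- atom_table(1:9, rep(c("N", "CA", "O"), 3),
                      rep(c("N", "C", "O"), 3), rep("GLY", 9),
                      rep(1:3, each = 3), "A")
  set.seed(51)
  xyz <- matrix(runif(27, 0, 12), ncol = 3)
  frames <- lapply(1:5, function(i) make_frame(atoms, xyz, index = i))
  cl <- cluster_frames(make_trajectory(frames), window = 1:5, cutoff_A = 1.5)
  expect_length(cl$centroids, 1L)
  expect_equal(cl$dispersion_A, 0, tolerance = 1e-9)

  fam <- two_family_trajectory(sizes = c(5L, 3L))
  cl2 <- cluster_frames(fam$traj, window = seq_along(fam$family),
                        cutoff_A = 2.0)
  expect_length(cl2$centroids, 2L)
  expect_equal(sort(tabulate(cl2$assignments)), c(3L, 5L))
  # members of one planted family share one cluster id
  expect_equal(length(unique(cl2$assignments[fam$family == 1L])), 1L)
  expect_error(cluster_frames(fam$traj, window = integer(0)), "empty")
})

test_that("cluster dispersion equals the mean member-to-centroid RMSD", {
  fam <- two_family_trajectory(sizes = c(6L), jitter = 0.3, seed = 61)
  cl <- cluster_frames(fam$traj, window = 1:6, cutoff_A = 2.0)
  expect_length(cl$centroids, 1L)
  cen <- make_frame(fam$traj$atoms, cl$centroids[[1L]])
  direct <- mean(vapply(1:6, function(i) {
    superpose(get_frame(fam$traj, i), cen)$rmsd
  }, numeric(1)))
  expect_equal(cl$dispersion_A, direct, tolerance = 1e-6)
})
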