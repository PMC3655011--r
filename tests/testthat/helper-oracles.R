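# Independent oracles and fixture builders shared across test files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# O(n^2) all-pairs intermolecular distance scan; returns sorted serial pairs.
brute_contact_pairs <- function(frame, chain_pair, threshold) {
  a <- frame$atoms
  ii <- which(a$chain == chain_pair[1L])
  jj <- which(a$chain == chain_pair[2L])
  out <- character(0)
  for (i in ii) for (j in jj) {
    d <- sqrt(sum((frame$xyz[i, ] - frame$xyz[j, ])^2))
    if (d <= threshold) out <- c(out, paste(a$serial[i], a$serial[j]))
  }
  sort(out)
}

contact_pairs_of <- function(events) {
  sort(paste(events$serial_i, events$serial_j))
}

# random two-chain frame with atoms uniform in a cube of side `box`
random_two_chain_frame <- function(n_atoms, box = 10) {
  n1 <- ceiling(n_atoms / 2)
  atoms <- atom_table(seq_len(n_atoms),
                     rep("CA", n_atoms), rep("C", n_atoms),
                     rep("GLY", n_atoms),
                     rep(seq_len(n_atoms), each = 1L),
                     c(rep("A", n1), rep("B", n_atoms - n1)))
  make_frame(atoms, matrix(runif(3 * n_atoms, 0, box), ncol = 3))
}

euler_rot <- function(p) {
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, 3, byrow = TRUE)
  ry <- function(t) matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)),
                           3, 3, byrow = TRUE)
  rz(p[1]) %*% ry(p[2]) %*% rz(p[3])
}

# brute-force minimum RMSD over proper rotations: coarse Euler-angle grid
# followed by quasi-Newton refinement; independent of the SVD route.
brute_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  f <- function(p) sqrt(mean(rowSums((A %*% t(euler_rot(p)) - B)^2)))
  grid <- as.matrix(expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                                b = seq(0, pi, length.out = 7),
                                c = seq(0, 2 * pi, length.out = 13)[-13]))
  vals <- apply(grid, 1L, f)
  best <- grid[which.min(vals), ]
  for (k in 1:3)
    best <- optim(best, f, method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 500))$par
  f(best)
}

# contact table carrying the published dimer-1 interface residue lists;
# each row pairs one GCP4 (chain B) residue with one gamma-tubulin
# (chain D) residue so that both full lists are represented.
paper_dimer1_contacts <- function() {
  gcp4 <- list(c("GLU", 367), c("GLN", 370), c("LEU", 404), c("GLN", 508),
               c("ARG", 515), c("ARG", 517), c("ASN", 518), c("ASP", 525),
               c("LEU", 531), c("GLN", 532), c("VAL", 533), c("LEU", 536),
               c("GLU", 537), c("SER", 538))
  gtub <- list(c("ARG", 2), c("ARG", 46), c("ASP", 48), c("PRO", 245),
               c("GLY", 246), c("MET", 248), c("ASN", 249), c("ILE", 260),
               c("ILE", 317), c("ILE", 328), c("ALA", 329), c("ILE", 330),
               c("LEU", 331), c("ASN", 332), c("GLN", 356), c("ILE", 443),
               c("TRP", 445))
  n <- max(length(gcp4), length(gtub))
  gi <- gcp4[((seq_len(n) - 1L) %% length(gcp4)) + 1L]
  gj <- gtub[((seq_len(n) - 1L) %% length(gtub)) + 1L]
  data.frame(
    chain_i = "B", resno_i = vapply(gi, function(x) as.integer(x[2]), 1L),
    resname_i = vapply(gi, `[`, "", 1), name_i = "CA",
    serial_i = seq_len(n),
    chain_j = "D", resno_j = vapply(gj, function(x) as.integer(x[2]), 1L),
    resname_j = vapply(gj, `[`, "", 1), name_j = "CA",
    serial_j = 1000L + seq_len(n),
    n_frames_present = 95L, n_frames_total = 100L,
    persistence_fraction = 0.95, stringsAsFactors = FALSE)
}

# two-family trajectory: `sizes` frames per conformer family, families
# separated by a large coordinated displacement, tiny within-family jitter
two_family_trajectory <- function(sizes, shift = 30, jitter = 0.05,
                                  seed = 99) {
  set.seed(seed)
  n_res <- 4L
  atoms <- atom_table(seq_len(3L * n_res), rep(c("N", "CA", "O"), n_res),
                      rep(c("N", "C", "O"), n_res),
                      rep("GLY", 3L * n_res),
                      rep(seq_len(n_res), each = 3L), "A")
  base <- matrix(runif(9L * n_res, 0, 15), ncol = 3)
  fam_of <- rep(seq_along(sizes), sizes)
  fam_of <- sample(fam_of)   # interleave membership
  frames <- lapply(seq_along(fam_of), function(f) {
    xyz <- base + matrix(rnorm(length(base), 0, jitter), ncol = 3)
    if (fam_of[f] == 2L) xyz[1:3, ] <- xyz[1:3, ] + shift
    make_frame(atoms, xyz, index = f)
  })
  list(traj = make_trajectory(frames), family = fam_of)
}
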