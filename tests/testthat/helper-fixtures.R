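# Shared fixtures: a reproducible toy fold, its ANM modes, and a planted
# ensemble at the generator's default settings. Built once per test run.

tt_fold <- make_toy_fold(60L, 11L, seed = 1L)
tt_hessian <- build_hessian(tt_fold$model, r_cut = 15, gamma = 1)
tt_anm <- anm_modes(tt_hessian)
tt_truth <- planted_truth(driver_mode_index = 1L, loop = tt_fold$loop,
                          amplitude = 2, noise_sigma = 0.3, m = 20L, seed = 7L)
tt_ensemble <- suppressWarnings(plant_ensemble(tt_fold$model, tt_truth))
tt_driver <- attr(tt_ensemble, "driver")
tt_coeff <- attr(tt_ensemble, "coefficients")
tt_aligned <- iterative_superpose_ensemble(tt_ensemble)
tt_pca <- ensemble_pca(tt_aligned)
tt_open <- tt_ensemble[[which.min(tt_coeff)]]
tt_closed <- tt_ensemble[[which.max(tt_coeff)]]
tt_defvec <- deformation_vector(tt_open, tt_closed)

# a hand-written PDB text for structure_io tests
write_tiny_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom_line <- function(eleno, elety, alt, resid, chain, resno, x, y, z,
                          occ = 1, b = 10, type = "ATOM", insert = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          type, eleno, paste0(" ", elety), alt, resid, chain, resno, insert,
          x, y, z, occ, b)
}

# orthonormal basis of rigid-body displacements, coded independently of the
# package internals (used as an oracle)
oracle_rigid_basis <- function(xyz) {
  n <- nrow(xyz)
  cen <- colMeans(xyz)
  b <- matrix(0, 3 * n, 6)
  for (a in 1:3) b[seq(a, 3 * n, by = 3), a] <- 1
  for (i in seq_len(n)) {
    r <- xyz[i, ] - cen
    b[(3 * i - 2):(3 * i), 4] <- c(0, -r[3], r[2])
    b[(3 * i - 2):(3 * i), 5] <- c(r[3], 0, -r[1])
    b[(3 * i - 2):(3 * i), 6] <- c(-r[2], r[1], 0)
  }
  qr.Q(qr(b))
}

expect_lm_error <- function(expr, class) {
  expect_error(expr, class = class)
}
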