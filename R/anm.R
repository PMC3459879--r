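# Anisotropic network model: Hessian assembly, normal modes, per-residue
# fluctuation profiles, B-factor comparison and mode collectivity.

#' Build the ANM Hessian for a C-alpha network
#'
#' Nodes are C-alpha atoms; pairs within `r_cut` are connected by uniform
#' springs of constant `gamma`. The 3 x 3 off-diagonal superblock for a
#' connected pair (i, j) is -gamma * R_ij R_ij^T / |R_ij|^2 evaluated at the
#' input (equilibrium) coordinates, and diagonal superblocks are minus the sum
#' of the off-diagonal superblocks in their row, so rigid translations cost no
#' energy.
#'
#' @param coords N x 3 C-alpha coordinates (Angstrom), or a [coarse_model()].
#' @param r_cut contact cutoff distance in Angstrom (default 15).
#' @param gamma uniform spring constant (arbitrary units; every downstream
#'   statistic used here is invariant to it).
#' @return Object of class `hessian_model`: list with `hessian` (3N x 3N),
#'   `kirchhoff` (N x N 0/1 contact matrix, zero diagonal), `coords`, `r_cut`,
#'   `gamma`, and `keys` when built from a model.
#' @export
build_hessian <- function(coords, r_cut = 15, gamma = 1) {
  keys <- NULL
  if (inherits(coords, "coarse_model")) {
    keys <- keys_table(coords)
    coords <- coords$xyz
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop_lm("need at least 3 residues", "shape_error")
  if (r_cut <= 0) stop_lm("r_cut must be positive", "parameter_error")
  if (gamma <= 0) stop_lm("gamma must be positive", "parameter_error")

  d2 <- as.matrix(stats::dist(coords))^2
  gam <- (d2 <= r_cut^2) * 1
  diag(gam) <- 0

  comp <- connected_components(gam)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop_lm(sprintf("network disconnected at r_cut = %g A: %d components (sizes %s)",
                    r_cut, max(comp), paste(sizes, collapse = ", ")),
            "connectivity_error")
  }

  H <- matrix(0, 3 * n, 3 * n)
  pairs <- which(upper.tri(gam) & gam > 0, arr.ind = TRUE)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- coords[j, ] - coords[i, ]
    blk <- -gamma * tcrossprod(r) / sum(r * r)
    ii <- idx3(i); jj <- idx3(j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  structure(list(hessian = H, kirchhoff = gam, coords = unname(coords),
                 r_cut = r_cut, gamma = gamma, keys = keys),
            class = "hessian_model")
}

#' @export
print.hessian_model <- function(x, ...) {
  cat(sprintf("hessian_model: N = %d, r_cut = %g A, gamma = %g, %d contacts\n",
              nrow(x$coords), x$r_cut, x$gamma, sum(x$kirchhoff) / 2))
  invisible(x)
}

# orthonormal basis of the 6 rigid-body displacement generators
rigid_body_basis <- function(coords) {
  n <- nrow(coords)
  cen <- colMeans(coords)
  rel <- sweep(coords, 2, cen)
  gens <- matrix(0, 3 * n, 6)
  for (a in 1:3) gens[seq(a, 3 * n, by = 3), a] <- 1      # translations
  axes <- diag(3)
  for (a in 1:3) {                                        # infinitesimal rotations
    cr <- cbind(axes[a, 2] * rel[, 3] - axes[a, 3] * rel[, 2],
                axes[a, 3] * rel[, 1] - axes[a, 1] * rel[, 3],
                axes[a, 1] * rel[, 2] - axes[a, 2] * rel[, 1])
    gens[, 3 + a] <- xyz_to_vec(cr)
  }
  qr.Q(qr(gens))[, seq_len(qr(gens)$rank), drop = FALSE]
}

#' ANM normal modes
#'
#' Diagonalizes the Hessian and returns the 3N - 6 internal modes sorted by
#' ascending eigenvalue (mode 1 = softest). The six near-zero rigid-body
#' eigenvalues (below 1e-8 of the largest) are discarded; more than six
#' near-zero eigenvalues indicates a degenerate (e.g. collinear) network.
#'
#' @param hm a [build_hessian()] result.
#' @return A [mode_set()] of kind `"anm"`.
#' @export
anm_modes <- function(hm) {
  if (!inherits(hm, "hessian_model")) stop_lm("expected a hessian_model", "shape_error")
  eg <- eigen(hm$hessian, symmetric = TRUE)
  vals <- rev(eg$values)                 # ascending
  vecs <- eg$vectors[, rev(seq_along(vals)), drop = FALSE]
  zero <- vals < 1e-8 * max(vals)
  nzero <- sum(zero)
  if (nzero > 6L)
    stop_lm(sprintf("%d near-zero eigenvalues (expected 6): degenerate network", nzero),
            "degeneracy_error")
  if (nzero < 6L)
    stop_lm(sprintf("only %d near-zero eigenvalues (expected 6)", nzero),
            "degeneracy_error")
  keys <- hm$keys
  if (is.null(keys))
    keys <- data.frame(chain = rep("A", nrow(hm$coords)),
                       resno = seq_len(nrow(hm$coords)),
                       insert = "", stringsAsFactors = FALSE)
  mode_set(vecs[, !zero, drop = FALSE], vals[!zero], kind = "anm",
           ref_xyz = hm$coords, keys = keys)
}

#' Per-residue square fluctuations driven by selected modes
#'
#' For each residue i, sum_j |u_i^(j)|^2 / lambda_j over the selected modes:
#' the ANM prediction of mean-square fluctuation (up to the global kT/gamma
#' scale), comparable to crystallographic B-factors.
#'
#' @param modes an ANM [mode_set()].
#' @param subset mode indices (default 1, the softest mode).
#' @return Nonnegative numeric vector of length N.
#' @export
mode_square_fluctuations <- function(modes, subset = 1L) {
  if (!inherits(modes, "mode_set")) stop_lm("expected a mode_set", "shape_error")
  if (length(subset) == 0L) stop_lm("subset must be non-empty", "index_error")
  if (any(subset < 1L) || any(subset > modes$k))
    stop_lm("mode index out of range", "index_error")
  out <- numeric(modes$N)
  for (j in subset) {
    u2 <- rowSums(vec_to_xyz(modes$vectors[, j])^2)
    out <- out + u2 / modes$values[j]
  }
  out
}

#' Pearson correlation between theoretical and experimental B-factors
#'
#' Scale- and offset-invariant, so neither the spring constant nor the
#' 8*pi^2/3 conversion needs fixing.
#'
#' @param theoretical,experimental equal-length per-residue vectors (>= 3).
#' @return Correlation coefficient in [-1, 1].
#' @export
bfactor_correlation <- function(theoretical, experimental) {
  if (length(theoretical) != length(experimental))
    stop_lm("vectors must have equal length", "shape_error")
  if (length(theoretical) < 3L) stop_lm("need at least 3 residues", "shape_error")
  if (stats::sd(theoretical) == 0 || stats::sd(experimental) == 0)
    stop_lm("constant vector: correlation undefined", "undefined_correlation_error")
  stats::cor(theoretical, experimental)
}

#' Degree of collectivity of a mode
#'
#' Entropy-based measure of how many residues a mode engages:
#' kappa = (1/N) * exp(-sum_i q_i log q_i) with q_i the normalized squared
#' residue amplitude (sum_i q_i = 1). kappa = 1 when every residue moves with
#' equal amplitude and 1/N when a single residue carries all the motion.
#'
#' @param mode a 3N numeric vector (one mode), or a [mode_set()] together
#'   with `index`.
#' @param index mode index when `mode` is a `mode_set`.
#' @return Collectivity in (0, 1].
#' @export
collectivity <- function(mode, index = 1L) {
  if (inherits(mode, "mode_set")) mode <- mode$vectors[, index]
  if (length(mode) %% 3L != 0L) stop_lm("mode length must be 3N", "shape_error")
  nm2 <- sum(mode^2)
  if (nm2 < 1e-24) stop_lm("zero mode vector", "degenerate_input_error")
  u2 <- rowSums(vec_to_xyz(mode)^2) / nm2
  n <- length(u2)
  pos <- u2 > 0
  exp(-sum(u2[pos] * log(u2[pos]))) / n
}
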