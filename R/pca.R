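# PCA of superposed conformer ensembles: covariance matrix, principal modes
# and variance fractions, and the two-structure deformation vector.

#' Mode set container
#'
#' Ordered orthonormal 3N-dimensional mode vectors with their eigenvalues,
#' tied to the reference coordinates and residue keys on which they were
#' computed. PCA eigenvalues (variances, Angstrom^2) are sorted descending;
#' ANM stiffness eigenvalues ascending (softest first); random surrogate sets
#' carry the eigenvalues they were paired with.
#'
#' @param vectors 3N x k matrix, one unit-norm mode per column.
#' @param values length-k eigenvalues.
#' @param kind one of `"pca"`, `"anm"`, `"random"`.
#' @param ref_xyz N x 3 reference coordinates.
#' @param keys data frame with columns chain / resno / insert (N rows).
#' @param fractions optional variance fractions (PCA).
#' @return Object of class `mode_set`.
#' @export
mode_set <- function(vectors, values, kind = c("pca", "anm", "random"),
                     ref_xyz, keys, fractions = NULL) {
  kind <- match.arg(kind)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != 3L * nrow(ref_xyz))
    stop_lm("mode length must be 3N for N reference residues", "shape_error")
  if (length(values) != ncol(vectors))
    stop_lm("one eigenvalue per mode required", "shape_error")
  g <- crossprod(vectors)
  if (max(abs(g - diag(ncol(vectors)))) > 1e-6)
    stop_lm("mode vectors are not orthonormal", "shape_error")
  structure(list(vectors = unname(vectors), values = as.numeric(values),
                 kind = kind, ref_xyz = unname(as.matrix(ref_xyz)),
                 keys = keys, fractions = fractions,
                 k = ncol(vectors), N = nrow(ref_xyz)),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set (%s): %d modes over %d residues\n", x$kind, x$k, x$N))
  invisible(x)
}

#' Positional covariance matrix of an aligned ensemble
#'
#' C = 1/(m-1) * sum_s dR^s (dR^s)^T over the 3N-dimensional deviations of
#' each superposed structure from the ensemble mean.
#'
#' @param ensemble an [iterative_superpose_ensemble()] result.
#' @return Symmetric positive-semidefinite 3N x 3N matrix (Angstrom^2), of
#'   rank at most min(3N, m - 1).
#' @export
covariance_matrix <- function(ensemble) {
  if (!inherits(ensemble, "aligned_ensemble"))
    stop_lm("expected an aligned_ensemble", "shape_error")
  if (ensemble$m < 2L) stop_lm("need at least two structures", "ensemble_size_error")
  mu <- xyz_to_vec(ensemble$mean_xyz)
  D <- vapply(ensemble$coords, function(x) xyz_to_vec(x) - mu,
              numeric(length(mu)))
  (D %*% t(D)) / (ensemble$m - 1L)
}

#' Principal modes of a covariance matrix
#'
#' Diagonalizes the experimental covariance matrix; eigenpairs are sorted by
#' descending variance and eigenvalues below 1e-10 of the largest are
#' truncated. Fractions f_i = sigma_i / sum_j sigma_j are computed over the
#' retained modes.
#'
#' @param C symmetric PSD 3N x 3N covariance matrix.
#' @param ref_xyz N x 3 reference coordinates (e.g. the ensemble mean).
#' @param keys residue key table matching `ref_xyz`.
#' @return A [mode_set()] of kind `"pca"` with variance `fractions`.
#' @export
principal_modes <- function(C, ref_xyz, keys) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    stop_lm("covariance matrix must be symmetric", "shape_error")
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  # variances below 1e-14 A^2 are numerically zero for atomic coordinates
  if (max(eg$values) < 1e-14)
    stop_lm("covariance matrix is numerically zero", "degenerate_input_error")
  keep <- eg$values > 1e-10 * max(eg$values)
  vals <- eg$values[keep]
  mode_set(eg$vectors[, keep, drop = FALSE], vals, kind = "pca",
           ref_xyz = ref_xyz, keys = keys, fractions = vals / sum(vals))
}

#' PCA of an aligned ensemble
#'
#' Convenience wrapper: [covariance_matrix()] followed by [principal_modes()]
#' with the ensemble mean as reference.
#'
#' @param ensemble an `aligned_ensemble`.
#' @return A [mode_set()] of kind `"pca"`.
#' @export
ensemble_pca <- function(ensemble) {
  principal_modes(covariance_matrix(ensemble), ensemble$mean_xyz, ensemble$keys)
}

#' Normalized open-to-closed deformation vector
#'
#' The unit 3N vector of C-alpha differences from the open to the closed
#' structure over their common residues, after optimal superposition of the
#' closed structure onto the open one.
#'
#' @param open,closed [coarse_model()]s sharing at least 3 residue keys.
#' @param superpose superpose `closed` onto `open` first (default TRUE; set
#'   FALSE when the two are already in a common frame).
#' @return Unit-norm numeric vector of length 3 * N_common, with attributes
#'   `keys` (residue key table), `ref_xyz` (open-structure coordinates) and
#'   `magnitude` (the unnormalized deformation norm, Angstrom).
#' @export
deformation_vector <- function(open, closed, superpose = TRUE) {
  keys <- common_keys(open, closed)
  if (length(keys) < (if (superpose) 3L else 1L))
    stop_lm("too few common residues", "correspondence_error")
  xo <- model_xyz_at(open, keys)
  xc <- model_xyz_at(closed, keys)
  if (superpose) xc <- apply_transform(xc, kabsch(xc, xo))
  d <- xyz_to_vec(xc - xo)
  nm <- vnorm(d)
  if (nm < 1e-8)
    stop_lm("structures are identical: degenerate deformation", "degenerate_difference_error")
  pos <- match(keys, model_keys(open))
  structure(d / nm,
            keys = data.frame(chain = open$chain[pos], resno = open$resno[pos],
                              insert = open$insert[pos], stringsAsFactors = FALSE),
            ref_xyz = xo, magnitude = nm)
}

#' Write a mode set to a plain-text file
#'
#' Documented format: a header (`kind`, `N`, `k`), one line of residue keys
#' (`chain|resno|insert`, space-separated), then for each mode one line with
#' the eigenvalue followed by one line with the 3N components, all at full
#' precision.
#'
#' @param modes a [mode_set()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_mode_set <- function(modes, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("kind", modes$kind),
               paste("N", modes$N),
               paste("k", modes$k),
               paste(residue_keys(modes$keys$chain, modes$keys$resno,
                                  modes$keys$insert), collapse = " ")), con)
  writeLines(paste(sprintf("%.17g", xyz_to_vec(modes$ref_xyz)), collapse = " "), con)
  for (j in seq_len(modes$k)) {
    writeLines(sprintf("%.17g", modes$values[j]), con)
    writeLines(paste(sprintf("%.17g", modes$vectors[, j]), collapse = " "), con)
  }
  invisible(file)
}

#' Read a mode set written by [write_mode_set()]
#'
#' @param file path to a mode-set text file.
#' @return A [mode_set()].
#' @export
read_mode_set <- function(file) {
  ln <- readLines(file)
  kind <- sub("^kind ", "", ln[1])
  n <- as.integer(sub("^N ", "", ln[2]))
  k <- as.integer(sub("^k ", "", ln[3]))
  key_parts <- strsplit(strsplit(ln[4], " ", fixed = TRUE)[[1]], "|", fixed = TRUE)
  keys <- data.frame(chain = vapply(key_parts, `[`, "", 1),
                     resno = as.integer(vapply(key_parts, `[`, "", 2)),
                     insert = vapply(key_parts, function(p)
                       if (length(p) >= 3) p[3] else "", ""),
                     stringsAsFactors = FALSE)
  ref <- vec_to_xyz(as.numeric(strsplit(ln[5], " +")[[1]]))
  vals <- numeric(k)
  vecs <- matrix(0, 3 * n, k)
  for (j in seq_len(k)) {
    vals[j] <- as.numeric(ln[4 + 2 * j])
    vecs[, j] <- as.numeric(strsplit(ln[5 + 2 * j], " +")[[1]])
  }
  mode_set(vecs, vals, kind = kind, ref_xyz = ref, keys = keys,
           fractions = if (kind == "pca") vals / sum(vals) else NULL)
}
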