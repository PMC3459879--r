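# Kabsch superposition and ensemble alignment, plus the open/closed deviation
# metrics (overall RMSD, loop RMSD after global alignment, isolated-loop RMSD,
# loop tip displacement).

#' Contiguous residue segment (e.g. the catalytic loop)
#'
#' @param chain chain identifier.
#' @param start_residue,end_residue inclusive author residue numbers.
#' @return Object of class `segment_selection`.
#' @export
segment_selection <- function(chain, start_residue, end_residue) {
  if (end_residue < start_residue)
    stop_lm("end_residue must be >= start_residue", "selection_error")
  structure(list(chain = as.character(chain),
                 start_residue = as.integer(start_residue),
                 end_residue = as.integer(end_residue)),
            class = "segment_selection")
}

#' @export
print.segment_selection <- function(x, ...) {
  cat(sprintf("segment %s:%d-%d\n", x$chain, x$start_residue, x$end_residue))
  invisible(x)
}

# residue indices of a segment within a key table (chain/resno/insert columns)
segment_indices <- function(keys, segment) {
  idx <- which(keys$chain == segment$chain &
                 keys$resno >= segment$start_residue &
                 keys$resno <= segment$end_residue)
  if (length(idx) == 0L)
    stop_lm(sprintf("segment %s:%d-%d selects no residues", segment$chain,
                    segment$start_residue, segment$end_residue),
            "selection_error")
  idx
}

keys_table <- function(model) {
  data.frame(chain = model$chain, resno = model$resno, insert = model$insert,
             stringsAsFactors = FALSE)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) RMSD of `mobile` onto `reference`. Reflections are excluded.
#'
#' @param mobile,reference N x 3 coordinate matrices with matching rows.
#' @param weights optional nonnegative per-residue weights (default uniform).
#' @return A list of class `rigid_transform` with elements `rotation` (3 x 3,
#'   determinant +1), `translation` (length 3) and `rmsd` (Angstrom). The
#'   transform maps row vectors as `x %*% rotation + translation`.
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop_lm("mobile and reference must be N x 3 with equal N", "shape_error")
  n <- nrow(mobile)
  if (n < 3L) stop_lm("need at least 3 points", "shape_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop_lm("weights must be nonnegative with positive sum", "shape_error")
  w <- weights / sum(weights)

  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  M <- sweep(mobile, 2, cm)
  Rf <- sweep(reference, 2, cr)

  # degeneracy: the point sets must span at least a plane
  if (sum(svd(M * sqrt(w))$d > 1e-8 * max(1, vnorm(M))) < 2 ||
      sum(svd(Rf * sqrt(w))$d > 1e-8 * max(1, vnorm(Rf))) < 2)
    stop_lm("degenerate (collinear or coincident) point set", "degeneracy_error")

  H <- t(M) %*% (Rf * w)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- as.vector(cr - cm %*% rot)
  moved <- mobile %*% rot + matrix(tr, n, 3, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((moved - reference)^2)))
  structure(list(rotation = rot, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz N x 3 coordinate matrix.
#' @param transform a `rigid_transform` from [kabsch()].
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz %*% transform$rotation +
    matrix(transform$translation, nrow(xyz), 3, byrow = TRUE)
}

# correspondence between two models: ordered common residue keys
common_keys <- function(a, b) {
  ka <- model_keys(a); kb <- model_keys(b)
  keep <- ka %in% kb
  ka[keep]
}

model_xyz_at <- function(model, keys) {
  pos <- match(keys, model_keys(model))
  if (anyNA(pos)) stop_lm("model lacks requested residues", "correspondence_error")
  model$xyz[pos, , drop = FALSE]
}

#' Iterative Kabsch superposition of a structure ensemble
#'
#' Superposes every model onto the running mean structure over the residues
#' common to all models, recomputing the mean until it moves less than
#' `tolerance` (RMS) between iterations. The first model's frame seeds the
#' mean.
#'
#' @param models list of two or more [coarse_model()]s.
#' @param tolerance convergence threshold on the mean structure's RMS
#'   displacement between iterations (Angstrom).
#' @param max_iter iteration cap; non-convergence yields a warning, not an
#'   error.
#' @return An object of class `aligned_ensemble`: list with `models` (full
#'   models, transformed into the common frame), `keys` (data frame of the
#'   common residue correspondence), `coords` (m-list of N_common x 3
#'   matrices), `mean_xyz`, `m`, and `iterations`.
#' @export
iterative_superpose_ensemble <- function(models, tolerance = 1e-5,
                                         max_iter = 100L) {
  if (length(models) < 2L) stop_lm("need at least two models", "ensemble_size_error")
  keys <- Reduce(function(k, m) k[k %in% model_keys(m)],
                 models[-1], model_keys(models[[1]]))
  if (length(keys) < 3L)
    stop_lm("common residue correspondence has fewer than 3 residues",
            "correspondence_error")
  coords <- lapply(models, model_xyz_at, keys = keys)
  mean_xyz <- coords[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (i in seq_along(models)) {
      tf <- kabsch(coords[[i]], mean_xyz)
      coords[[i]] <- apply_transform(coords[[i]], tf)
      models[[i]]$xyz <- apply_transform(models[[i]]$xyz, tf)
    }
    new_mean <- Reduce(`+`, coords) / length(coords)
    shift <- sqrt(mean(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tolerance) break
    if (iter >= max_iter) {
      warning(sprintf("ensemble superposition did not converge in %d iterations (last shift %.2e A)",
                      max_iter, shift), call. = FALSE)
      break
    }
  }
  first <- models[[1]]
  pos <- match(keys, model_keys(first))
  structure(list(models = models,
                 keys = data.frame(chain = first$chain[pos],
                                   resno = first$resno[pos],
                                   insert = first$insert[pos],
                                   stringsAsFactors = FALSE),
                 coords = coords,
                 mean_xyz = mean_xyz,
                 m = length(models),
                 iterations = iter),
            class = "aligned_ensemble")
}

#' @export
print.aligned_ensemble <- function(x, ...) {
  cat(sprintf("aligned_ensemble: %d models, %d common residues, %d iteration(s)\n",
              x$m, nrow(x$keys), x$iterations))
  invisible(x)
}

#' RMSD between two structures over a selection
#'
#' Computes the C-alpha RMSD over `selection` after superposing on
#' `align_on`. With `align_on = "all"` and a loop selection this is the loop
#' deviation in the whole-protein frame; with `align_on = "selection"` it is
#' the isolated (internal) loop RMSD.
#'
#' @param a,b [coarse_model()]s sharing residue keys.
#' @param selection a [segment_selection()] or `"all"`.
#' @param align_on `"all"` or `"selection"`.
#' @return RMSD in Angstrom.
#' @export
rmsd_selection <- function(a, b, selection = "all",
                           align_on = c("all", "selection")) {
  align_on <- match.arg(align_on)
  keys <- common_keys(a, b)
  if (length(keys) < 3L)
    stop_lm("fewer than 3 common residues", "correspondence_error")
  xa <- model_xyz_at(a, keys)
  xb <- model_xyz_at(b, keys)
  pos <- match(keys, model_keys(a))
  ktab <- data.frame(chain = a$chain[pos], resno = a$resno[pos],
                     insert = a$insert[pos], stringsAsFactors = FALSE)
  sel_idx <- if (identical(selection, "all")) seq_along(keys)
             else segment_indices(ktab, selection)
  align_idx <- if (align_on == "all") seq_along(keys) else sel_idx
  tf <- kabsch(xb[align_idx, , drop = FALSE], xa[align_idx, , drop = FALSE])
  xb_fit <- apply_transform(xb, tf)
  sqrt(mean(rowSums((xb_fit[sel_idx, , drop = FALSE] -
                       xa[sel_idx, , drop = FALSE])^2)))
}

#' Loop tip displacement between two structures
#'
#' After whole-protein superposition, the maximum per-residue C-alpha
#' displacement within the loop. The residue attaining it is the loop "tip".
#'
#' @param a,b [coarse_model()]s sharing residue keys.
#' @param loop a [segment_selection()].
#' @return Displacement in Angstrom, with attributes `tip_resno` and
#'   `tip_chain`.
#' @export
tip_displacement <- function(a, b, loop) {
  keys <- common_keys(a, b)
  if (length(keys) < 3L)
    stop_lm("fewer than 3 common residues", "correspondence_error")
  xa <- model_xyz_at(a, keys)
  xb <- model_xyz_at(b, keys)
  tf <- kabsch(xb, xa)
  xb_fit <- apply_transform(xb, tf)
  pos <- match(keys, model_keys(a))
  ktab <- data.frame(chain = a$chain[pos], resno = a$resno[pos],
                     insert = a$insert[pos], stringsAsFactors = FALSE)
  li <- segment_indices(ktab, loop)
  disp <- sqrt(rowSums((xb_fit[li, , drop = FALSE] - xa[li, , drop = FALSE])^2))
  tip <- which.max(disp)
  structure(max(disp), tip_resno = ktab$resno[li[tip]],
            tip_chain = ktab$chain[li[tip]])
}
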