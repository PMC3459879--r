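# Mode-comparison statistics: overlap, cumulative overlap, segment (loop)
# overlap, weighted-average overlap over mode windows, sliding-window
# profiles, the random-orthonormal-mode null, difference profiles and
# enhancement factors.

as_mode_vector <- function(x, j = NULL) {
  if (inherits(x, "mode_set")) x$vectors[, if (is.null(j)) 1L else j] else as.numeric(x)
}

normalize_checked <- function(v, what) {
  nm <- vnorm(v)
  if (nm < 1e-12) stop_lm(sprintf("%s is a zero vector", what), "degenerate_input_error")
  if (abs(nm - 1) > 1e-6)
    warning(sprintf("%s was not unit-norm (|v| = %.6g); normalized", what, nm),
            call. = FALSE)
  v / nm
}

#' Overlap (absolute correlation cosine) between two direction vectors
#'
#' O = |a . b| for unit vectors a, b; inputs are normalized internally (with a
#' warning) if they are not.
#'
#' @param a,b numeric vectors of equal length (typically 3N).
#' @return Overlap in [0, 1].
#' @export
overlap <- function(a, b) {
  a <- as_mode_vector(a); b <- as_mode_vector(b)
  if (length(a) != length(b)) stop_lm("vectors differ in length", "shape_error")
  a <- normalize_checked(a, "first vector")
  b <- normalize_checked(b, "second vector")
  min(abs(sum(a * b)), 1)
}

#' Cumulative overlap of a reference deformation with the first J modes
#'
#' CO_J = sqrt(sum_{j=1}^{J} O_j^2) with O_j the per-mode overlap. Over the
#' complete 3N - 6 ANM basis (for a reference orthogonal to the rigid-body
#' space) CO equals 1.
#'
#' @param ref unit reference vector (3N).
#' @param modes a [mode_set()].
#' @param J number of leading modes to accumulate (default: all).
#' @return Cumulative overlap in [0, 1] (up to rounding).
#' @export
cumulative_overlap <- function(ref, modes, J = modes$k) {
  if (J < 1L || J > modes$k) stop_lm("J out of range", "index_error")
  ref <- normalize_checked(as_mode_vector(ref), "reference")
  if (length(ref) != nrow(modes$vectors))
    stop_lm("reference and modes differ in dimension", "shape_error")
  ov <- as.vector(crossprod(modes$vectors[, seq_len(J), drop = FALSE], ref))
  sqrt(sum(ov^2))
}

#' Per-mode and cumulative overlap profile
#'
#' @param ref unit reference vector (3N), e.g. PC1 or a deformation vector.
#' @param modes a [mode_set()].
#' @param reference_label label recorded in the output.
#' @return Data frame with columns `mode`, `overlap`, `cumulative` and
#'   `cumulative_sq` (CO^2, the explained-variance reading of the curve).
#' @export
overlap_profile <- function(ref, modes, reference_label = "reference") {
  ref <- normalize_checked(as_mode_vector(ref), "reference")
  ov <- abs(as.vector(crossprod(modes$vectors, ref)))
  data.frame(reference = reference_label, mode = seq_len(modes$k),
             overlap = ov, cumulative = sqrt(cumsum(ov^2)),
             cumulative_sq = cumsum(ov^2))
}

# 3s-element indices of a residue-index set
segment_vector_indices <- function(res_idx) idx3(res_idx)

segment_res_indices <- function(keys, segment) {
  if (inherits(segment, "segment_selection")) segment_indices(keys, segment)
  else as.integer(segment)
}

#' Segment (loop) overlap between two 3N vectors
#'
#' Restricts both vectors to the 3s components of an s-residue segment,
#' renormalizes each subvector to unit length, and returns their absolute dot
#' product ("orientational" overlap, independent of how much amplitude either
#' vector places on the segment).
#'
#' @param ref,mode 3N numeric vectors (or `mode_set` for `mode` with `j`).
#' @param segment a [segment_selection()] or integer residue indices.
#' @param keys residue key table positioning the segment (taken from `ref`'s
#'   `keys` attribute or the mode set when omitted).
#' @param j mode column when `mode` is a `mode_set`.
#' @return Overlap in [0, 1].
#' @export
segment_overlap <- function(ref, mode, segment, keys = NULL, j = 1L) {
  if (is.null(keys)) {
    keys <- attr(ref, "keys")
    if (is.null(keys) && inherits(mode, "mode_set")) keys <- mode$keys
  }
  if (is.null(keys) && !inherits(segment, "segment_selection")) {
    # plain index segment needs no key table
    keys <- NULL
  } else if (is.null(keys)) {
    stop_lm("residue keys required to resolve a segment_selection", "selection_error")
  }
  ref <- as_mode_vector(ref); mv <- as_mode_vector(mode, j)
  if (length(ref) != length(mv)) stop_lm("vectors differ in length", "shape_error")
  ri <- segment_res_indices(keys, segment)
  vi <- segment_vector_indices(ri)
  a <- ref[vi]; b <- mv[vi]
  if (vnorm(a) < 1e-10 || vnorm(b) < 1e-10)
    stop_lm("segment subvector has near-zero norm", "degenerate_segment_error")
  min(abs(sum((a / vnorm(a)) * (b / vnorm(b)))), 1)
}

# weights of modes for the weighted-average overlap
wao_weights <- function(vectors, values, vi, window,
                        weighting = c("amplitude_inv_eig", "amplitude", "uniform")) {
  weighting <- match.arg(weighting)
  amp2 <- colSums(vectors[vi, window, drop = FALSE]^2)
  switch(weighting,
         amplitude_inv_eig = amp2 / values[window],
         amplitude = amp2,
         uniform = rep(1, length(window)))
}

#' Weighted-average segment overlap over a window of modes
#'
#' <O|s>_p = sum_j w_j O_sj / sum_j w_j over the modes in `mode_window`,
#' where O_sj is the orientational segment overlap of mode j with `ref` and
#' the default weights w_j = |u_s^(j)|^2 / lambda_j combine the share of mode
#' amplitude the segment carries with the mode's thermal amplitude, so that
#' both the size and the orientation of the predicted segment motion enter.
#' A convex combination of values in [0, 1], hence itself in [0, 1].
#'
#' @param ref unit 3N reference vector.
#' @param modes a [mode_set()].
#' @param segment a [segment_selection()] or integer residue indices.
#' @param mode_window integer mode indices (default softest 10).
#' @param weighting `"amplitude_inv_eig"` (default), `"amplitude"` or
#'   `"uniform"`.
#' @param keys optional residue key table (see [segment_overlap()]).
#' @return Weighted-average overlap in [0, 1].
#' @export
weighted_average_overlap <- function(ref, modes, segment,
                                     mode_window = seq_len(min(10L, modes$k)),
                                     weighting = "amplitude_inv_eig",
                                     keys = NULL) {
  if (any(mode_window < 1L) || any(mode_window > modes$k))
    stop_lm("mode_window out of range", "window_error")
  if (is.null(keys)) keys <- modes$keys
  ri <- segment_res_indices(keys, segment)
  vi <- segment_vector_indices(ri)
  ref <- as_mode_vector(ref)
  w <- wao_weights(modes$vectors, modes$values, vi, mode_window, weighting)
  if (sum(w) <= 0)
    stop_lm("all mode weights vanish on this segment", "degenerate_window_error")
  o <- vapply(mode_window, function(j)
    segment_overlap(ref, modes$vectors[, j], ri), numeric(1))
  sum(w * o) / sum(w)
}

#' Weighted-average overlap profile over sliding mode windows
#'
#' Evaluates <O|s>_p for every contiguous window of `p` modes (1..p, 2..p+1,
#' ...) across the spectrum; the first entry is the softest-modes value.
#'
#' @inheritParams weighted_average_overlap
#' @param p window size in modes (default 10).
#' @return Data frame of class `window_profile` with columns `axis`,
#'   `window_start`, `value`.
#' @export
mode_window_profile <- function(ref, modes, segment, p = 10L,
                                weighting = "amplitude_inv_eig", keys = NULL) {
  if (p > modes$k) stop_lm("window size exceeds mode count", "window_error")
  starts <- seq_len(modes$k - p + 1L)
  vals <- vapply(starts, function(s)
    weighted_average_overlap(ref, modes, segment, s:(s + p - 1L), weighting, keys),
    numeric(1))
  out <- data.frame(axis = "mode-window", window_start = starts, value = vals)
  class(out) <- c("window_profile", class(out))
  out
}

#' Random orthonormal mode sets (null model)
#'
#' Draws sets of Gaussian random 3N vectors, projects out the six rigid-body
#' generators of the reference coordinates, orthonormalizes them in order, and
#' pairs the r-th vector with the r-th supplied eigenvalue — surrogate modes
#' with the same spectrum but random directions.
#'
#' @param ref_xyz N x 3 reference coordinates (define the rigid-body space).
#' @param eigenvalues positive eigenvalues taken from the source mode window.
#' @param count number of independent sets.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @param keys optional residue key table for the resulting sets.
#' @return List of `count` [mode_set()]s of kind `"random"`.
#' @export
random_modeset <- function(ref_xyz, eigenvalues, count = 1L, seed = NULL,
                           keys = NULL) {
  ref_xyz <- as.matrix(ref_xyz)
  n3 <- 3L * nrow(ref_xyz)
  p <- length(eigenvalues)
  if (count < 1L) stop_lm("count must be >= 1", "parameter_error")
  if (any(eigenvalues <= 0)) stop_lm("eigenvalues must be positive", "parameter_error")
  if (n3 <= 6L + p)
    stop_lm("3N must exceed 6 + number of modes requested", "dimension_error")
  rigid <- rigid_body_basis(ref_xyz)
  if (is.null(keys))
    keys <- data.frame(chain = rep("A", nrow(ref_xyz)),
                       resno = seq_len(nrow(ref_xyz)), insert = "",
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    lapply(seq_len(count), function(s) {
      vecs <- matrix(0, n3, p)
      basis <- rigid
      for (r in seq_len(p)) {
        repeat {
          z <- stats::rnorm(n3)
          z <- z - basis %*% crossprod(basis, z)
          if (vnorm(z) > 1e-6) break
        }
        z <- z / vnorm(z)
        vecs[, r] <- z
        basis <- cbind(basis, z)
      }
      mode_set(vecs, eigenvalues, kind = "random", ref_xyz = ref_xyz,
               keys = keys)
    })
  })
}

# contiguous s-residue windows within each chain of a key table
sequence_windows <- function(keys, s) {
  out <- list()
  for (ch in unique(keys$chain)) {
    idx <- which(keys$chain == ch)
    if (length(idx) < s) next
    for (st in seq_len(length(idx) - s + 1L)) {
      win <- idx[st:(st + s - 1L)]
      out[[length(out) + 1L]] <- list(chain = ch, idx = win,
                                      start_resno = keys$resno[win[1]])
    }
  }
  out
}

#' Sequence-window difference profile and loop enhancement factor
#'
#' Slides an s-residue window along each chain and evaluates the
#' weighted-average overlap of the reference deformation with the `p` softest
#' ANM modes, and with `n_random` random orthonormal mode sets carrying the
#' same eigenvalues. The difference profile (ANM minus random baseline)
#' highlights segments whose observed reconfiguration is preferentially
#' carried by the soft modes; the enhancement factor is the ANM/random ratio
#' at the catalytic loop window.
#'
#' @param ref unit 3N reference vector (deformation vector or PC1).
#' @param modes an ANM [mode_set()].
#' @param loop the catalytic loop, a [segment_selection()]; its length in the
#'   correspondence sets the window size s.
#' @param p number of softest modes averaged (default 10).
#' @param n_random number of random mode sets for the baseline (default 100).
#' @param seed seed for the random sets.
#' @param weighting weighting scheme, see [weighted_average_overlap()].
#' @param keys optional residue key table (defaults to the mode set's).
#' @return List of class `enhancement_analysis`: `profile` (data frame:
#'   chain, window_start resno, anm, random, difference), `enhancement_factor`,
#'   `loop_anm`, `loop_random`, `loop_random_se`, `s`, `p`, `n_random`.
#' @export
enhancement_analysis <- function(ref, modes, loop, p = 10L, n_random = 100L,
                                 seed = NULL, weighting = "amplitude_inv_eig",
                                 keys = NULL) {
  if (n_random < 1L) stop_lm("n_random must be >= 1", "parameter_error")
  if (is.null(keys)) keys <- modes$keys
  loop_idx <- segment_res_indices(keys, loop)
  s <- length(loop_idx)
  window <- seq_len(min(p, modes$k))
  rand_sets <- random_modeset(modes$ref_xyz, modes$values[window],
                              count = n_random, seed = seed, keys = keys)
  wins <- sequence_windows(keys, s)

  eval_window <- function(idx) {
    anm_val <- tryCatch(
      weighted_average_overlap(ref, modes, idx, window, weighting, keys),
      loopmodes_error = function(e) NA_real_)
    rnd <- vapply(rand_sets, function(rs) tryCatch(
      weighted_average_overlap(ref, rs, idx, seq_along(window), weighting, keys),
      loopmodes_error = function(e) NA_real_), numeric(1))
    c(anm_val, mean(rnd, na.rm = TRUE), stats::sd(rnd) / sqrt(sum(!is.na(rnd))))
  }

  prof <- t(vapply(wins, function(w) eval_window(w$idx), numeric(3)))
  profile <- data.frame(chain = vapply(wins, `[[`, "", "chain"),
                        window_start = vapply(wins, function(w) w$start_resno, 0),
                        anm = prof[, 1], random = prof[, 2],
                        difference = prof[, 1] - prof[, 2])
  n_skipped <- sum(is.na(profile$anm) | is.na(profile$random))
  if (n_skipped > 0)
    message(sprintf("%d degenerate window(s) skipped", n_skipped))

  lv <- eval_window(loop_idx)
  structure(list(profile = profile,
                 enhancement_factor = lv[1] / lv[2],
                 loop_anm = lv[1], loop_random = lv[2], loop_random_se = lv[3],
                 s = s, p = length(window), n_random = n_random,
                 loop = if (inherits(loop, "segment_selection")) loop else NULL),
            class = "enhancement_analysis")
}

#' @export
print.enhancement_analysis <- function(x, ...) {
  cat(sprintf("enhancement_analysis: s = %d, p = %d, %d random sets\n",
              x$s, x$p, x$n_random))
  cat(sprintf("  loop <O|s>_p: ANM %.3f, random %.3f (se %.3g) -> enhancement %.2f\n",
              x$loop_anm, x$loop_random, x$loop_random_se, x$enhancement_factor))
  invisible(x)
}
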