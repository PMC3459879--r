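# Synthetic toy folds and planted-conformer ensembles. The generator emulates
# the statistical structure the analysis assumes: a multi-conformer C-alpha
# ensemble whose dominant variation is a displacement along one low-frequency
# collective mode of the fold, with a designated protruding "loop" carrying a
# large share of that mode's amplitude, plus isotropic Gaussian noise.

#' Ground truth for a planted synthetic ensemble
#'
#' @param driver_mode_index which ANM mode of the fold drives the ensemble.
#' @param loop the designated loop, a [segment_selection()].
#' @param amplitude RMS per-residue displacement (Angstrom) along the driver
#'   mode at |c| = 1.
#' @param noise_sigma isotropic per-coordinate Gaussian noise (Angstrom).
#' @param m conformer count.
#' @param seed integer seed.
#' @param coefficients optional explicit per-conformer coefficients c_s
#'   (overrides the random draw).
#' @return Object of class `planted_truth`.
#' @export
planted_truth <- function(driver_mode_index = 1L, loop = NULL, amplitude = 2,
                          noise_sigma = 0.3, m = 20L, seed = 7L,
                          coefficients = NULL) {
  if (amplitude <= 0) stop_lm("amplitude must be positive", "parameter_error")
  if (noise_sigma < 0) stop_lm("noise_sigma must be >= 0", "parameter_error")
  if (m < 2L) stop_lm("m must be >= 2", "parameter_error")
  structure(list(driver_mode_index = as.integer(driver_mode_index), loop = loop,
                 amplitude = amplitude, noise_sigma = noise_sigma,
                 m = as.integer(m), seed = seed, coefficients = coefficients),
            class = "planted_truth")
}

# one attempt at a compact self-avoiding chain with a protruding hairpin
.attempt_fold <- function(n, loop_len, loop_start) {
  bond <- 3.8
  min_sep <- 3.5
  radius <- 2.7 * n^(1/3)
  loop_end <- loop_start + loop_len - 1L
  half <- ceiling(loop_len / 2)
  xyz <- matrix(NA_real_, n, 3)
  xyz[1, ] <- c(0, 0, 0)
  for (i in 2:n) {
    cur <- xyz[i - 1, ]
    cen <- colMeans(xyz[seq_len(i - 1), , drop = FALSE])
    placed <- FALSE
    for (try in 1:300) {
      if (i >= loop_start && i <= loop_end) {
        out_dir <- cur - cen
        if (vnorm(out_dir) < 1e-6) out_dir <- c(0, 0, 1)
        out_dir <- out_dir / vnorm(out_dir)
        if (i < loop_start + half) {
          dir <- out_dir + 0.2 * stats::rnorm(3)       # extend outward
        } else {
          anchor <- xyz[loop_start - 1, ] + 2.5 * bond * out_dir
          back <- anchor - cur
          if (vnorm(back) < 1e-6) back <- -out_dir
          dir <- back / vnorm(back) + 0.2 * stats::rnorm(3)   # turn back
        }
      } else {
        dir <- stats::rnorm(3)
        drift <- cur - cen
        excess <- vnorm(drift) - radius
        if (excess > 0)                                 # harmonic compaction
          dir <- dir - (0.8 + 0.4 * excess) * drift / vnorm(drift)
        if (i > n - 4L && vnorm(drift) > 0.5 * radius)  # bury the C-terminus
          dir <- dir - 0.8 * drift / vnorm(drift)
      }
      dir <- dir / vnorm(dir)
      cand <- cur + bond * dir
      prev <- xyz[seq_len(i - 2L), , drop = FALSE]
      if (i == 2L || nrow(prev) == 0L ||
          min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  xyz
}

#' Generate a compact toy fold with a protruding loop
#'
#' Builds a self-avoiding C-alpha chain (consecutive distance 3.8 Angstrom)
#' compacted into a globule of radius proportional to n^(1/3), carrying one
#' protruding hairpin of `loop_length` residues near the middle of the chain.
#' The hairpin makes fewer contacts than the core, so the soft ANM modes of
#' the fold naturally localize amplitude there. The result is guaranteed
#' connected at a 15-Angstrom cutoff.
#'
#' @param n_residues chain length (>= 30).
#' @param loop_length hairpin length (>= 5 and < n_residues / 3).
#' @param seed integer seed; generation is reproducible.
#' @param max_attempts bounded retries before a generation error.
#' @return List with `model` (a [coarse_model()], chain "A", residues
#'   1..n_residues) and `loop` (a [segment_selection()]).
#' @export
make_toy_fold <- function(n_residues = 60L, loop_length = 11L, seed = 1L,
                          max_attempts = 60L) {
  n <- as.integer(n_residues); ll <- as.integer(loop_length)
  if (n < 30L) stop_lm("n_residues must be >= 30", "parameter_error")
  if (ll < 5L || ll >= n / 3) stop_lm("loop_length must be >= 5 and < n/3", "parameter_error")
  loop_start <- as.integer(floor((n - ll) / 2) + 1L)
  xyz <- with_seed(seed, {
    found <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- .attempt_fold(n, ll, loop_start)
      if (is.null(cand)) next
      gam <- (as.matrix(stats::dist(cand)) <= 15) * 1
      diag(gam) <- 0
      if (max(connected_components(gam)) == 1L) {
        found <- cand
        break
      }
    }
    if (is.null(found))
      stop_lm(sprintf("failed to generate a connected fold in %d attempts", max_attempts),
              "generation_error")
    found
  })
  model <- coarse_model(id = sprintf("toy_n%d_l%d_s%s", n, ll, format(seed)),
                        chain = rep("A", n), resno = seq_len(n),
                        xyz = xyz, bfactor = 1)
  list(model = model,
       loop = segment_selection("A", loop_start, loop_start + ll - 1L))
}

#' Plant a conformer ensemble along one ANM mode of a fold
#'
#' Conformer s = fold + c_s * amplitude * sqrt(N) * u + noise, where u is the
#' (unit 3N) driver mode, so that |c_s| = 1 corresponds to an RMS per-residue
#' displacement of `amplitude` Angstrom. Coefficients c_s are drawn as
#' sign * Uniform(0.5, 1) with half the signs negative ("open") and half
#' positive ("closed"), so representative open/closed extraction is well
#' posed. B-factors are set proportional to the planted per-residue variance.
#'
#' @param fold result of [make_toy_fold()], or a [coarse_model()].
#' @param truth a [planted_truth()].
#' @param r_cut ANM cutoff used to obtain the driver mode (default 15).
#' @return List of `truth$m` [coarse_model()]s, with attributes `driver`
#'   (the unit 3N driver mode), `coefficients` and `truth`.
#' @export
plant_ensemble <- function(fold, truth, r_cut = 15) {
  model <- if (inherits(fold, "coarse_model")) fold else fold$model
  modes <- anm_modes(build_hessian(model, r_cut = r_cut))
  if (truth$driver_mode_index < 1L || truth$driver_mode_index > modes$k)
    stop_lm("driver_mode_index out of range", "index_error")
  u <- modes$vectors[, truth$driver_mode_index]
  n <- model$N
  disp <- vec_to_xyz(u) * truth$amplitude * sqrt(n)

  cs <- truth$coefficients
  if (is.null(cs)) {
    cs <- with_seed(truth$seed, {
      sign <- rep(c(-1, 1), length.out = truth$m)
      sign * stats::runif(truth$m, 0.5, 1)
    })
  }
  if (length(cs) != truth$m)
    stop_lm("coefficients must have length m", "parameter_error")

  # planted per-residue mean-square fluctuation -> surrogate B-factor
  msf <- stats::var(cs) * rowSums(disp^2) + 3 * truth$noise_sigma^2
  bf <- (8 * pi^2 / 3) * msf

  ens <- with_seed(truth$seed + 1L, {
    lapply(seq_len(truth$m), function(s) {
      noise <- if (truth$noise_sigma > 0)
        matrix(stats::rnorm(3 * n, sd = truth$noise_sigma), n, 3) else 0
      xyz <- model$xyz + cs[s] * disp + noise
      coarse_model(id = sprintf("%s_conf%02d", model$id, s),
                   chain = model$chain, resno = model$resno, xyz = xyz,
                   bfactor = bf, insert = model$insert)
    })
  })
  bonds <- sqrt(rowSums((ens[[which.max(abs(cs))]]$xyz[-1, ] -
                           ens[[which.max(abs(cs))]]$xyz[-n, ])^2))
  if (any(bonds > 1.5 * 3.8))
    warning("planted amplitude stretches bonds beyond 150% of ideal; geometry unphysical but analysis remains valid",
            call. = FALSE)
  structure(ens, driver = u, coefficients = cs, truth = truth)
}

#' Write a planted ensemble as PDB files plus a truth sidecar
#'
#' One PDB file per conformer and a plain-text `truth.txt` recording the
#' planted parameters (keys: driver_mode_index, loop, amplitude, noise_sigma,
#' m, seed, coefficients).
#'
#' @param ensemble result of [plant_ensemble()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(ensemble)) {
    f <- file.path(dir, sprintf("conf%02d.pdb", i))
    write_structure(ensemble[[i]], f)
    files <- c(files, f)
  }
  truth <- attr(ensemble, "truth")
  if (!is.null(truth)) {
    tf <- file.path(dir, "truth.txt")
    lines <- c(paste("driver_mode_index", truth$driver_mode_index),
               if (!is.null(truth$loop))
                 paste("loop", truth$loop$chain, truth$loop$start_residue,
                       truth$loop$end_residue),
               paste("amplitude", truth$amplitude),
               paste("noise_sigma", truth$noise_sigma),
               paste("m", truth$m),
               paste("seed", truth$seed),
               paste("coefficients",
                     paste(sprintf("%.17g", attr(ensemble, "coefficients")),
                           collapse = " ")))
    writeLines(lines, tf)
    files <- c(files, tf)
  }
  invisible(files)
}
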