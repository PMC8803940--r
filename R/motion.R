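#' Motion-artifact specification
#'
#' Parameters of the segmented k-space rigid-motion simulator.  During an
#' MPRAGE-like acquisition the k-space is filled line by line along one
#' phase-encode axis; a head movement ("nod") between segments leaves a
#' block of lines acquired in a displaced pose, which produces ghosting and
#' ringing in the reconstructed image.
#'
#' @param n_nods number of discrete motion events (contiguous corrupted
#'   k-space blocks); the study generator uses 5 and 10 for its two active
#'   head-motion conditions.
#' @param max_translation_mm peak rigid displacement per nod.
#' @param max_rotation_deg peak rotation per nod.
#' @param corrupted_fraction fraction of phase-encode lines acquired in a
#'   displaced pose, in [0, 1].
#' @param seed random seed for block placement and per-nod poses.
#' @return a \code{motion_spec} list.
#' @export
motion_spec <- function(n_nods = 5, max_translation_mm = 1.5,
                        max_rotation_deg = 1.5, corrupted_fraction = 0.3,
                        seed = 1) {
  stopifnot(n_nods >= 0, max_translation_mm >= 0, max_rotation_deg >= 0,
            corrupted_fraction >= 0, corrupted_fraction <= 1)
  structure(list(n_nods = as.integer(n_nods),
                 max_translation_mm = max_translation_mm,
                 max_rotation_deg = max_rotation_deg,
                 corrupted_fraction = corrupted_fraction,
                 seed = seed), class = "motion_spec")
}

fft_freqs <- function(n) (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n

#' Apply simulated head-motion artifacts to a volume
#'
#' Forward 3D Fourier transform; the phase-encode lines (third array axis,
#' anterior-posterior) are partitioned so that \code{n_nods} contiguous
#' blocks covering about \code{corrupted_fraction} of the lines are replaced
#' by the transform of a rigidly displaced copy of the image: translations
#' enter exactly as linear phase ramps, rotations by image-domain
#' resampling before the transform.  The magnitude of the inverse transform
#' is returned.  Only intensities are affected; ground-truth masks are
#' untouched by design.
#'
#' @param v a conformed \code{brain_volume}.
#' @param m a \code{\link{motion_spec}}.
#' @return the corrupted \code{brain_volume}; deterministic given
#'   \code{m$seed}.
#' @export
apply_motion <- function(v, m) {
  stopifnot(is_volume(v), inherits(m, "motion_spec"))
  d <- dim(v$data)
  n_corrupt <- round(m$corrupted_fraction * d[3])
  if (n_corrupt == 0 || m$n_nods == 0 ||
      (m$max_translation_mm == 0 && m$max_rotation_deg == 0)) {
    # no k-space segment is displaced: the acquisition is consistent and
    # reconstruction returns the image unchanged
    return(v)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(m$seed)

  blk_len <- max(1L, n_corrupt %/% m$n_nods)
  starts <- sort(sample.int(max(1L, d[3] - blk_len + 1L), m$n_nods,
                            replace = m$n_nods > d[3] - blk_len + 1L))
  K <- stats::fft(v$data)
  f1 <- fft_freqs(d[1]); f2 <- fft_freqs(d[2]); f3 <- fft_freqs(d[3])
  for (b in seq_len(m$n_nods)) {
    lines_b <- seq.int(starts[b], min(starts[b] + blk_len - 1L, d[3]))
    trans_mm <- stats::runif(3, -1, 1) * m$max_translation_mm
    rot_deg <- stats::runif(3, -1, 1) * m$max_rotation_deg
    trans_vox <- trans_mm / v$spacing
    Kb <- if (any(rot_deg != 0)) {
      stats::fft(rotate_array(v$data, rot_deg, order = 1, fill = 0))
    } else K
    # separable linear phase ramp for the rigid translation
    ramp1 <- exp(-2i * pi * f1 * trans_vox[1])
    ramp2 <- exp(-2i * pi * f2 * trans_vox[2])
    ramp3 <- exp(-2i * pi * f3 * trans_vox[3])
    blk <- Kb[, , lines_b, drop = FALSE] * ramp1
    blk <- sweep(blk, 2, ramp2, `*`)
    blk <- sweep(blk, 3, ramp3[lines_b], `*`)
    K[, , lines_b] <- blk
  }
  x <- Mod(stats::fft(K, inverse = TRUE)) / prod(d)
  as_volume(x, spacing = v$spacing, orientation = v$orientation)
}

#' Motion severity score and quality grading
#'
#' The severity of a motion spec is
#' \code{corrupted_fraction * (max_translation_mm + c * max_rotation_deg)}
#' with \code{c = 50 * pi / 180} mm/degree, i.e. rotations are converted to
#' an equivalent edge displacement at a 50 mm head radius.  The score is
#' monotone nondecreasing in every magnitude parameter and zero for
#' motion-free specs.
#'
#' @param m a \code{\link{motion_spec}}.
#' @return \code{severity_score}: a nonnegative scalar.
#' @export
severity_score <- function(m) {
  stopifnot(inherits(m, "motion_spec"))
  m$corrupted_fraction * (m$max_translation_mm +
                            (50 * pi / 180) * m$max_rotation_deg)
}

#' @rdname severity_score
#' @param thresholds two increasing severity cut points; scores at or below
#'   the first grade HM1, at or below the second HM2, above it HM3.  Ties
#'   break toward the better tier.
#' @return \code{grade_quality}: one of \code{"HM1"}, \code{"HM2"},
#'   \code{"HM3"} (ordered factor levels of increasing artifact severity).
#' @export
grade_quality <- function(m, thresholds = c(0.5, 2.0)) {
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  s <- severity_score(m)
  if (s <= thresholds[1]) "HM1" else if (s <= thresholds[2]) "HM2" else "HM3"
}
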