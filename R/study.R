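#' Generate a synthetic head-motion study
#'
#' Emulates the structure of a head-motion acquisition campaign: for each
#' synthetic subject one motion-free record (CONV), one record with a
#' 5-nod motion design (MOVE1) and one with a 10-nod design (MOVE2) are
#' produced from the same phantom anatomy, each MOVE record with its own
#' randomly jittered motion magnitudes and a resulting quality tier
#' (HM1/HM2/HM3).  Optionally, \code{n_retest} additional motion-free
#' records per subject (fresh noise, identical anatomy) emulate repeated
#' sessions for test-retest designs.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param seed run seed; every phantom, motion draw and noise draw derives
#'   its own seed from it.
#' @param out_dir directory for NIfTI volumes/masks and the roster CSV.
#' @param n_retest repeated motion-free records per subject (default 0).
#' @param shape phantom grid (default desk-scale 64^3).
#' @param noise_sd phantom noise level.
#' @param move1,move2 base \code{\link{motion_spec}}-like parameter lists
#'   for the two motion conditions (fields \code{n_nods},
#'   \code{max_translation_mm}, \code{max_rotation_deg},
#'   \code{corrupted_fraction}); per-record magnitudes are scaled by a
#'   random factor in [0.5, 1.5].
#' @param thresholds severity cut points passed to \code{\link{grade_quality}}.
#' @return the roster data frame (also written to
#'   \code{out_dir/roster.csv}) with columns \code{subject},
#'   \code{condition}, \code{session}, \code{tier}, \code{severity},
#'   \code{volume}, \code{mask}, \code{seed}.
#' @export
generate_study <- function(n_subjects, seed, out_dir, n_retest = 0,
                           shape = c(64, 64, 64), noise_sd = 4,
                           move1 = list(n_nods = 5, max_translation_mm = 1.2,
                                        max_rotation_deg = 1.2,
                                        corrupted_fraction = 0.25),
                           move2 = list(n_nods = 10, max_translation_mm = 2.5,
                                        max_rotation_deg = 2.5,
                                        corrupted_fraction = 0.5),
                           thresholds = c(0.5, 2.0)) {
  stopifnot(n_subjects >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in seq_len(n_subjects)) {
    anat_seed <- derive_seed(seed, "phantom", s)
    spec <- phantom_spec(shape = shape, noise_sd = noise_sd, seed = anat_seed)
    ph <- generate_phantom(spec)
    mask_path <- file.path(out_dir, sprintf("sub%03d_mask.nii.gz", s))
    write_nifti(ph$mask, mask_path)

    record <- function(condition, session, vol, mspec) {
      vol_path <- file.path(out_dir,
                            sprintf("sub%03d_%s.nii.gz", s, condition))
      write_nifti(vol, vol_path)
      sev <- if (is.null(mspec)) 0 else severity_score(mspec)
      tier <- if (is.null(mspec)) "HM1" else grade_quality(mspec, thresholds)
      data.frame(subject = sprintf("sub%03d", s), condition = condition,
                 session = session, tier = tier, severity = sev,
                 volume = vol_path, mask = mask_path,
                 seed = anat_seed, stringsAsFactors = FALSE)
    }

    rows[[length(rows) + 1]] <- record("CONV", 1L, ph$volume, NULL)
    for (cond in c("MOVE1", "MOVE2")) {
      base <- if (cond == "MOVE1") move1 else move2
      mseed <- derive_seed(seed, "motion", s, cond)
      fac <- with_seed(mseed, stats::runif(1, 0.5, 1.5))
      mspec <- motion_spec(n_nods = base$n_nods,
                           max_translation_mm = base$max_translation_mm * fac,
                           max_rotation_deg = base$max_rotation_deg * fac,
                           corrupted_fraction = base$corrupted_fraction,
                           seed = derive_seed(mseed, "apply"))
      vol <- apply_motion(ph$volume, mspec)
      rows[[length(rows) + 1]] <- record(cond, if (cond == "MOVE1") 2L else 3L,
                                         vol, mspec)
    }
    if (n_retest > 0) {
      for (r in seq_len(n_retest)) {
        rspec <- phantom_spec(shape = shape, noise_sd = noise_sd,
                              seed = anat_seed,
                              noise_seed = derive_seed(seed, "retest", s, r))
        rph <- generate_phantom(rspec)
        rows[[length(rows) + 1]] <- record(sprintf("RETEST%d", r), 3L + r,
                                           rph$volume, NULL)
      }
    }
  }
  roster <- do.call(rbind, rows)
  utils::write.csv(roster, file.path(out_dir, "roster.csv"),
                   row.names = FALSE)
  roster
}
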