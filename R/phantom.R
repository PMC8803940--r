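#' Phantom specification
#'
#' Parameters of the synthetic labeled head phantom: a scalp ellipsoid
#' (Unknown label, nonzero intensity), a cortical shell split into four
#' quadrant parcels, a white-matter core, paired ventricles, and
#' \code{n_subcortical} ellipsoidal nuclei arranged on a ring inside the
#' white matter.  Each tissue has a mean intensity (arbitrary T1-like
#' units); cortical parcels and nuclei get deterministic per-label offsets
#' so regions are distinguishable by intensity as well as by geometry.
#' All structure sizes scale with \code{shape}, and the phantom head is
#' sized so that the brain always fits the fixed crop box of the matching
#' \code{\link{pipeline_geometry}}.
#'
#' @param shape voxel grid, at least 32 per axis; default desk-scale 64^3.
#' @param n_subcortical number of nucleus blobs (default 4).
#' @param tissue_intensities named vector with entries \code{scalp},
#'   \code{csf}, \code{cortex}, \code{wm}, \code{nucleus}.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed seed controlling subject anatomy (center/size jitter).
#' @param noise_seed seed for the noise draw only; defaults to a value
#'   derived from \code{seed}.  Repeated "sessions" of the same subject use
#'   the same \code{seed} with different \code{noise_seed}s.
#' @param jitter relative anatomical jitter of center and radii (default 0.04).
#' @return a \code{phantom_spec} list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), n_subcortical = 4,
                         tissue_intensities = c(scalp = 45, csf = 30,
                                                cortex = 55, wm = 125,
                                                nucleus = 78),
                         noise_sd = 4, seed = 1, noise_seed = NULL,
                         jitter = 0.04) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 32), noise_sd >= 0,
            n_subcortical >= 0, jitter >= 0)
  req <- c("scalp", "csf", "cortex", "wm", "nucleus")
  if (!all(req %in% names(tissue_intensities)))
    stop("tissue_intensities must name: ", paste(req, collapse = ", "))
  if (is.null(noise_seed)) noise_seed <- derive_seed(seed, "noise")
  structure(list(shape = shape, n_subcortical = n_subcortical,
                 tissue_intensities = tissue_intensities,
                 noise_sd = noise_sd, seed = seed, noise_seed = noise_seed,
                 jitter = jitter), class = "phantom_spec")
}

# squared normalized ellipsoid coordinate for every voxel
ellipsoid_q <- function(I, J, K, ctr, semi) {
  ((I - ctr[1]) / semi[1])^2 + ((J - ctr[2]) / semi[2])^2 +
    ((K - ctr[3]) / semi[3])^2
}

#' Generate a labeled head phantom
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param scheme the active \code{\link{label_scheme}}; cortical parcels use
#'   its first four cortical ids, nuclei its first \code{n_subcortical}
#'   subcortical ids, plus the white-matter and ventricle labels.
#' @return a list with elements \code{volume} (a \code{brain_volume}) and
#'   \code{mask} (the ground-truth \code{label_mask}); deterministic given
#'   the spec's seeds.
#' @export
generate_phantom <- function(spec, scheme = default_scheme()) {
  stopifnot(inherits(spec, "phantom_spec"))
  sub_ids <- scheme_ids_of(scheme, "subcortical")
  cor_ids <- scheme_ids_of(scheme, "cortical")
  if (spec$n_subcortical > length(sub_ids))
    stop("n_subcortical = ", spec$n_subcortical, " exceeds the ",
         length(sub_ids), " subcortical ids in the scheme")
  if (length(cor_ids) < 4) stop("scheme must provide >= 4 cortical ids")
  wm_id <- scheme$id[scheme$name == "cerebral-white-matter"]
  vent_id <- scheme$id[scheme$name == "ventricles"]
  if (length(wm_id) != 1 || length(vent_id) != 1)
    stop("scheme must contain 'cerebral-white-matter' and 'ventricles' entries")

  d <- spec$shape
  S <- min(d)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  jit <- function(n) stats::runif(n, -spec$jitter, spec$jitter)
  ctr <- (d + 1) / 2 + jit(3) * S
  rscl <- 1 + jit(1)

  I <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  J <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  K <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)

  head_semi <- c(0.40, 0.42, 0.44) * S * rscl
  brain_semi <- c(0.27, 0.28, 0.32) * S * rscl
  wm_semi <- brain_semi * 0.78

  q_head <- ellipsoid_q(I, J, K, ctr, head_semi)
  q_brain <- ellipsoid_q(I, J, K, ctr, brain_semi)
  q_wm <- ellipsoid_q(I, J, K, ctr, wm_semi)

  ti <- spec$tissue_intensities
  intens <- array(0, d)
  labels <- array(0L, d)
  intens[q_head <= 1] <- ti[["scalp"]]

  # cortical ribbon, split into quadrant parcels with intensity offsets
  ribbon <- q_brain <= 1 & q_wm > 1
  quad <- 1L + (I > ctr[1]) + 2L * (K > ctr[3])
  for (p in 1:4) {
    sel <- ribbon & quad == p
    labels[sel] <- cor_ids[p]
    intens[sel] <- ti[["cortex"]] + (p - 1) * 8
  }
  labels[q_wm <= 1] <- wm_id
  intens[q_wm <= 1] <- ti[["wm"]]

  # paired ventricles
  vent_semi <- c(0.035, 0.05, 0.09) * S
  for (sgn in c(-1, 1)) {
    vc <- ctr + c(sgn * 0.06 * S, 0, 0)
    sel <- ellipsoid_q(I, J, K, vc, vent_semi) <= 1
    labels[sel] <- vent_id
    intens[sel] <- ti[["csf"]]
  }

  # nucleus ring in the (i, k) mid-plane; like real subcortical anatomy the
  # arrangement is stereotyped across subjects (fixed angular positions with
  # small individual jitter)
  if (spec$n_subcortical > 0) {
    nsemi <- c(0.06, 0.06, 0.065) * S
    for (m in seq_len(spec$n_subcortical)) {
      th <- pi / 8 + 2 * pi * (m - 1) / spec$n_subcortical +
        stats::runif(1, -0.05, 0.05)
      nc <- ctr + 0.155 * S * c(cos(th), 0, sin(th))
      sel <- ellipsoid_q(I, J, K, nc, nsemi) <= 1
      labels[sel] <- sub_ids[m]
      intens[sel] <- ti[["nucleus"]] + (m - 1) * 9
    }
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$noise_seed)
    intens <- intens + array(stats::rnorm(prod(d), sd = spec$noise_sd), d)
  }
  list(volume = as_volume(intens),
       mask = as_label_mask(labels, scheme))
}
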