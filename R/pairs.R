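#' Build mask pairs for a reliability design
#'
#' Two pairing designs are supported.  \code{head_motion}: for each
#' (subject, method) whose motion-free CONV record was graded HM1, the
#' CONV mask is the reference and every MOVE record contributes one pair
#' with pairing type \code{HM1-<tier of the MOVE record>}; subjects whose
#' CONV record is worse than HM1 contribute nothing (their exclusion is
#' recorded).  \code{test_retest}: every unordered within-(subject,
#' method) pair of records, the earlier session acting as ground truth,
#' pairing type \code{TR}.
#'
#' @param roster data frame with columns \code{subject}, \code{method},
#'   \code{condition}, \code{session}, \code{tier} and \code{mask} (path
#'   to the segmentation mask produced by \code{method} for that record).
#' @param design \code{"head_motion"} or \code{"test_retest"}.
#' @return data frame of pairs: \code{pair_id}, \code{subject},
#'   \code{method}, \code{pairing_type}, \code{ref_mask}, \code{cmp_mask};
#'   excluded subjects are listed in the \code{"excluded"} attribute.
#' @export
build_pairs <- function(roster, design = c("head_motion", "test_retest")) {
  design <- match.arg(design)
  need <- c("subject", "method", "condition", "session", "tier", "mask")
  if (!all(need %in% names(roster)))
    stop("roster must have columns: ", paste(need, collapse = ", "))
  rows <- list()
  excluded <- character()
  for (grp in split(roster, list(roster$subject, roster$method),
                    drop = TRUE)) {
    grp <- grp[order(grp$session), ]
    subj <- grp$subject[1]; meth <- grp$method[1]
    if (design == "head_motion") {
      ref <- grp[grp$condition == "CONV", ]
      if (nrow(ref) != 1 || ref$tier != "HM1") {
        excluded <- c(excluded,
                      sprintf("%s/%s: no HM1 CONV reference", subj, meth))
        next
      }
      moves <- grp[grepl("^MOVE", grp$condition), ]
      for (i in seq_len(nrow(moves))) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = subj, method = meth,
          pairing_type = paste0("HM1-", moves$tier[i]),
          ref_mask = ref$mask, cmp_mask = moves$mask[i],
          stringsAsFactors = FALSE)
      }
    } else {
      n <- nrow(grp)
      if (n >= 2) {
        for (i in 1:(n - 1)) for (j in (i + 1):n) {
          rows[[length(rows) + 1]] <- data.frame(
            subject = subj, method = meth, pairing_type = "TR",
            ref_mask = grp$mask[i], cmp_mask = grp$mask[j],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(pair_id = integer(), subject = character(),
                      method = character(), pairing_type = character(),
                      ref_mask = character(), cmp_mask = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[c("ref_mask", "cmp_mask")]), ]
    out <- cbind(pair_id = seq_len(nrow(out)), out)
  }
  if (length(excluded) > 0)
    message("excluded from pairing: ", paste(excluded, collapse = "; "))
  attr(out, "excluded") <- excluded
  out
}

#' Compute per-region metrics for a list of mask pairs
#'
#' Reads every mask pair and evaluates \code{\link{per_region_metrics}},
#' annotating each region row with the pair's subject, method and pairing
#' type.
#'
#' @param pairs data frame from \code{\link{build_pairs}}.
#' @param scheme the \code{\link{label_scheme}} of the masks.
#' @param percentile Hausdorff variant, see \code{\link{hausdorff}}.
#' @return the long metrics table (one row per pair and region).
#' @export
evaluate_pairs <- function(pairs, scheme, percentile = 1) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    ref <- read_nifti(pairs$ref_mask[i], scheme = scheme)
    cmp <- read_nifti(pairs$cmp_mask[i], scheme = scheme)
    m <- per_region_metrics(ref, cmp, percentile = percentile)
    cbind(pair_id = pairs$pair_id[i], subject = pairs$subject[i],
          method = pairs$method[i], pairing_type = pairs$pairing_type[i],
          m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
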