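#' Label schemes
#'
#' A label scheme maps integer segmentation ids to region names and
#' macro-regions (\code{cortical}, \code{subcortical} or \code{other}).
#' One id is designated the Unknown (background / out-of-brain) label; it is
#' used to pad predictions back to the full field of view and is never
#' treated as a region when metrics are computed.
#'
#' @param id integer vector of unique label ids.
#' @param name character vector of region names.
#' @param macro_region character vector, each one of \code{"cortical"},
#'   \code{"subcortical"}, \code{"other"}.
#' @param unknown_id id of the Unknown label; must appear in \code{id}.
#' @return an object of class \code{label_scheme}: a data frame with columns
#'   \code{id}, \code{name}, \code{macro_region} plus an \code{unknown_id}
#'   attribute.
#' @export
label_scheme <- function(id, name, macro_region, unknown_id = 0L) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("label ids must be unique")
  if (length(name) != length(id) || length(macro_region) != length(id))
    stop("id, name and macro_region must have equal length")
  if (!all(macro_region %in% c("cortical", "subcortical", "other")))
    stop("macro_region must be cortical, subcortical or other")
  if (!unknown_id %in% id) stop("unknown_id must be one of the scheme ids")
  out <- data.frame(id = id, name = as.character(name),
                    macro_region = as.character(macro_region),
                    stringsAsFactors = FALSE)
  attr(out, "unknown_id") <- as.integer(unknown_id)
  class(out) <- c("label_scheme", "data.frame")
  out
}

#' @rdname label_scheme
#' @param scheme a \code{label_scheme}.
#' @export
unknown_id <- function(scheme) attr(scheme, "unknown_id")

#' Default 50-label whole-brain scheme
#'
#' A Desikan-Killiany-style segmentation target with 50 entries in total:
#' the Unknown label (id 0), 34 cortical parcels merged across hemispheres,
#' 11 subcortical/cerebellar structures, and 4 further tissue classes
#' (cerebral white matter, a single merged ventricle label, CSF, choroid
#' plexus).  Fully replaceable via \code{\link{read_scheme}}.
#'
#' @return a \code{\link{label_scheme}} with 50 rows.
#' @export
default_scheme <- function() {
  cortical <- c(
    "bankssts", "caudal-anterior-cingulate", "caudal-middle-frontal",
    "cuneus", "entorhinal", "fusiform", "inferior-parietal",
    "inferior-temporal", "isthmus-cingulate", "lateral-occipital",
    "lateral-orbitofrontal", "lingual", "medial-orbitofrontal",
    "middle-temporal", "parahippocampal", "paracentral",
    "pars-opercularis", "pars-orbitalis", "pars-triangularis",
    "pericalcarine", "postcentral", "posterior-cingulate", "precentral",
    "precuneus", "rostral-anterior-cingulate", "rostral-middle-frontal",
    "superior-frontal", "superior-parietal", "superior-temporal",
    "supramarginal", "frontal-pole", "temporal-pole",
    "transverse-temporal", "insula")
  subcortical <- c(
    "thalamus", "caudate", "putamen", "pallidum", "hippocampus",
    "amygdala", "accumbens-area", "ventral-dc", "cerebellum-cortex",
    "cerebellum-white-matter", "brainstem")
  other <- c("cerebral-white-matter", "ventricles", "csf", "choroid-plexus")
  label_scheme(
    id = 0:49,
    name = c("unknown", cortical, subcortical, other),
    macro_region = c("other", rep("cortical", length(cortical)),
                     rep("subcortical", length(subcortical)),
                     rep("other", length(other))),
    unknown_id = 0L)
}

#' Read / write label schemes as plain text
#'
#' The on-disk format is whitespace-separated with columns
#' \code{id name macro_region}; FreeSurfer-LUT-style files (id and name as
#' the first two columns, extra colour columns ignored) are accepted, in
#' which case entries lacking a recognizable macro-region column are
#' assigned \code{"other"}.  Lines starting with \code{#} are comments.
#'
#' @param path file path.
#' @param unknown_id id of the Unknown label (default 0).
#' @return \code{read_scheme}: a \code{\link{label_scheme}}.
#' @export
read_scheme <- function(path, unknown_id = 0L) {
  if (!file.exists(path)) stop("scheme file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("scheme file needs at least id and name columns")
  macro <- if (ncol(tab) >= 3 &&
               all(tab[[3]] %in% c("cortical", "subcortical", "other"))) {
    tab[[3]]
  } else {
    rep("other", nrow(tab))
  }
  label_scheme(tab[[1]], tab[[2]], macro, unknown_id = unknown_id)
}

#' @rdname read_scheme
#' @param scheme a \code{\link{label_scheme}} to write.
#' @export
write_scheme <- function(scheme, path) {
  utils::write.table(as.data.frame(scheme), path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("label scheme:", nrow(x), "entries (unknown id ",
      attr(x, "unknown_id"), ")\n", sep = "")
  print(table(x$macro_region))
  invisible(x)
}

scheme_ids_of <- function(scheme, macro) scheme$id[scheme$macro_region == macro]
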