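#' Immune cell markers, tumor regions, and metastatic sites
#'
#' The analysis covers six immunohistochemistry markers quantified in three
#' tumor regions. Lymphocyte markers (CD3, CD4, CD8, FOXP3) are measured as
#' nuclear counts per area (cells/mm^2); macrophage markers (CD68, CD163) are
#' measured as positive pixel counts per area (pixels/mm^2). The unit is a
#' property of the marker family and is never converted.
#'
#' @return `markers()`, `regions()` and `metastatic_sites()` return character
#'   vectors of the valid enum tokens. `marker_family()` and `marker_unit()`
#'   return the family / unit for each marker given.
#' @examples
#' markers()
#' marker_unit("CD163")
#' @export
markers <- function() c("CD3", "CD4", "CD8", "FOXP3", "CD68", "CD163")

#' @rdname markers
#' @export
regions <- function() c("CT", "IM", "DM")

#' @rdname markers
#' @export
metastatic_sites <- function() {
  c("liver", "lung", "peritoneum", "non_regional_lymph_node", "ovary", "other")
}

#' @rdname markers
#' @param marker character vector of marker names.
#' @export
marker_family <- function(marker) {
  stop_if_bad_enum(marker, markers(), "marker")
  ifelse(marker %in% c("CD68", "CD163"), "macrophage", "lymphocyte")
}

#' @rdname markers
#' @export
marker_unit <- function(marker) {
  ifelse(marker_family(marker) == "macrophage",
         "pixels_per_mm2", "cells_per_mm2")
}

#' Reference density summaries for an advanced colorectal cancer cohort
#'
#' Published-scale medians, interquartile ranges and survival-derived cutoff
#' values of tumor-infiltrating immune cell densities per marker and region
#' in advanced colorectal cancer with distant metastasis. These anchor the
#' synthetic cohort generator's default log-normal parameters
#' (see [default_density_params()]) and provide ready-made cutoffs for worked
#' examples. Units: cells/mm^2 for lymphocyte markers, pixels/mm^2 for
#' macrophage markers.
#'
#' @return data.frame with columns `marker`, `region`, `median`, `q1`, `q3`,
#'   `cutoff`.
#' @export
crc_density_reference <- function() {
  ref <- data.frame(
    marker = rep(markers(), each = 3L),
    region = rep(c("CT", "IM", "DM"), times = 6L),
    median = c(297.79, 389.15, 76.27,
               98.01, 59.01, 238.52,
               112.24, 293.20, 235.68,
               11.67, 9.58, 9.36,
               340080.87, 330204.65, 500631.05,
               138787.44, 153225.53, 160636.11),
    q1 = c(154.13, 246.95, 28.04,
           38.30, 24.03, 94.42,
           48.42, 177.85, 91.52,
           2.92, 2.52, 2.72,
           229761.65, 233509.22, 318786.38,
           80061.73, 100686.21, 85120.41),
    q3 = c(516.33, 649.42, 204.55,
           241.05, 124.82, 506.93,
           232.98, 504.41, 648.20,
           33.33, 38.26, 23.27,
           480635.88, 485385.06, 844905.83,
           201969.89, 250086.39, 273752.28),
    cutoff = c(158.52, 321.15, 272.23,
               22.88, 82.25, 52.61,
               310.10, 164.67, 98.92,
               6.37, 0.71, 33.69,
               623734.20, 278123.90, 488839.60,
               328155.00, 230371.20, 53170.20),
    stringsAsFactors = FALSE
  )
  ref
}

# internal: error on tokens outside a closed enum
stop_if_bad_enum <- function(x, valid, what) {
  bad <- setdiff(unique(as.character(x)), valid)
  if (length(bad)) {
    stop(sprintf("invalid %s token(s): %s (valid: %s)", what,
                 paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
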