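#' Experimental group labels of a sample sheet
#'
#' Groups are the four (muscle, graft) combinations, written
#' \code{"EOM-pre"}, \code{"TA-post"}, etc. Matching is case-sensitive and
#' exact; the sample sheet is the single source of group membership.
#'
#' @param sheet sample sheet data.frame with columns \code{muscle} and
#'   \code{graft}.
#' @return character vector of group labels, one per sample.
#' @export
sampleGroups <- function(sheet) {
  paste(sheet$muscle, sheet$graft, sep = "-")
}

#' Validate a sample sheet
#'
#' @param sheet data.frame with columns sample_id, muscle, graft, donor_id.
#' @return the sheet, invisibly, after validation.
#' @export
validateSampleSheet <- function(sheet) {
  need <- c("sample_id", "muscle", "graft", "donor_id")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss))
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  bad <- setdiff(unique(sheet$muscle), VALID_MUSCLES)
  if (length(bad))
    stop("invalid muscle value(s): ", paste(bad, collapse = ", "),
         " (must be EOM or TA, case-sensitive)")
  bad <- setdiff(unique(sheet$graft), VALID_GRAFTS)
  if (length(bad))
    stop("invalid graft value(s): ", paste(bad, collapse = ", "),
         " (must be pre or post, case-sensitive)")
  invisible(sheet)
}

# columns (sample indices) belonging to one group label such as "TA-pre"
groupColumns <- function(sheet, group) {
  which(sampleGroups(sheet) == group)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# row means that tolerate all-NA rows without warnings
rowMeansNA <- function(m) {
  out <- rowMeans(m, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  out
}
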