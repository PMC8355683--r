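#' Per-shark summary table from the Lighthouse Reef Atoll study
#'
#' Loads the packaged per-shark summary for the 77 Caribbean reef sharks
#' tracked on the 18-receiver array at Lighthouse Reef Atoll, Belize
#' (2007--2014): sex, size class, tagging date, total length, days detected,
#' receivers visited, residency indices (RI on the 1877-day nominal tag life,
#' RI_max on the tagging-to-last-detection span), roaming index, and the 50%
#' kernel-density core activity space (km^2^; `NA` for the 9 animals with too
#' few relocations to estimate one).
#'
#' Indices are carried at their published 3-decimal precision. One tag id
#' (65) was deployed on both a female and a male, so rows are keyed by
#' (`shark_id`, `sex`).
#'
#' @return data.frame with 77 rows and columns `shark_id`, `sex`,
#'   `size_class`, `date_tagged`, `tl_cm`, `days_detected`,
#'   `receivers_visited`, `ri`, `ri_max`, `roaming_index`, `kd50_km2`.
#' @examples
#' tbl <- lighthouse_table1()
#' table(tbl$size_class)
#' @export
lighthouse_table1 <- function() {
  path <- system.file("extdata", "table1.csv", package = "atollnet", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(shark_id = "character"))
  tbl$date_tagged <- as.Date(tbl$date_tagged)
  tbl$sex <- factor(tbl$sex, levels = c("F", "M"))
  tbl
}
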