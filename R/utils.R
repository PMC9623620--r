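# internal helpers shared across modules

# canonical column order for calf datasets
ftpi_columns <- c("herd_id", "calf_id", "age_days",
                  "igg_rid", "stp_ba", "alb", "brix", "stp_op", "ggt")

ftpi_measurements <- c("igg_rid", "stp_ba", "alb", "brix", "stp_op", "ggt")

`%||%` <- function(x, y) if (is.null(x)) y else x

# coerce a character vector to numeric under the missing-token rules:
# "", "NA", "NaN" (case-insensitive) are silently missing; any other
# non-numeric token becomes missing with a warning naming it.
coerce_numeric <- function(x, field) {
  x <- trimws(as.character(x))
  blank <- is.na(x) | tolower(x) %in% c("", "na", "nan")
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(out)
  if (any(bad)) {
    warning(sprintf("column '%s': %d non-numeric value(s) treated as missing (e.g. \"%s\")",
                    field, sum(bad), x[which(bad)[1L]]), call. = FALSE)
  }
  out[blank] <- NA_real_
  out
}

# shared validation of the record-level invariants
validate_calf_data <- function(ds) {
  stopifnot(is.data.frame(ds))
  missing_cols <- setdiff(c("herd_id", "calf_id"), names(ds))
  if (length(missing_cols))
    stop("dataset lacks required column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(ds$herd_id, ds$calf_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- ds[duplicated(key), c("herd_id", "calf_id"), drop = FALSE][1L, ]
    stop(sprintf("duplicate (herd_id, calf_id) key: (%s, %s)", dup$herd_id, dup$calf_id))
  }
  for (v in intersect(c("age_days", ftpi_measurements), names(ds))) {
    x <- ds[[v]]
    if (any(!is.na(x) & (!is.finite(x) | x < 0)))
      stop(sprintf("column '%s' contains non-finite or negative values", v))
  }
  if ("brix" %in% names(ds)) {
    b <- ds$brix
    if (any(!is.na(b) & (b <= 0 | b >= 30)))
      stop("column 'brix' has values outside (0, 30); serum Brix is a percent, not a fraction")
  }
  invisible(ds)
}

set_provenance <- function(ds, text) {
  attr(ds, "provenance") <- c(attr(ds, "provenance"), text)
  ds
}

#' @noRd
get_provenance <- function(ds) attr(ds, "provenance")
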