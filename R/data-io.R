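#' Read a calf serology dataset from CSV
#'
#' Reads a flat comma-separated table of calf records: one row per calf with a
#' herd identifier, a calf identifier, age in days, the radial-immunodiffusion
#' (RID) IgG reference concentration, and up to five indirect measurements
#' (serum total protein by biochemistry analyzer `stp_ba` and by optical
#' refractometer `stp_op`, albumin `alb`, digital Brix `brix`, and
#' gamma-glutamyl transferase activity `ggt`).
#'
#' Empty cells and the tokens `"NA"` / `"NaN"` (case-insensitive) are missing
#' values; any other non-numeric token in a measurement column is treated as
#' missing with a warning. Structural problems (unreadable file, duplicate
#' `(herd_id, calf_id)` keys, negative or non-finite measurements, Brix outside
#' the physiological (0, 30) percent range) are errors.
#'
#' @param path path to a CSV file with a header row.
#' @param column_map optional named character vector mapping canonical column
#'   names (`herd_id`, `calf_id`, `age_days`, `igg_rid`, `stp_ba`, `alb`,
#'   `brix`, `stp_op`, `ggt`) to the header names used in the file, for files
#'   with non-canonical headers.
#' @return a `data.frame` with the canonical columns (measurement columns
#'   numeric, identifiers character) and a `"provenance"` attribute describing
#'   the source.
#' @seealso [write_calf_data()], [apply_age_filter()], [derive_fields()]
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("herd_id,calf_id,age_days,igg_rid,stp_ba,alb,brix,stp_op,ggt",
#'              "H1,C1,3,12.5,58,22,8.6,55,410",
#'              "H1,C2,4,7.2,49,21,,47,250"), path)
#' read_calf_data(path)
read_calf_data <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), ftpi_columns)
    if (length(bad)) stop("unknown canonical name(s) in column_map: ",
                          paste(bad, collapse = ", "))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop(sprintf("column_map: header '%s' (for '%s') not found in file", src, canon))
      names(raw)[names(raw) == src] <- canon
    }
  }
  out <- list()
  n <- nrow(raw)
  for (v in ftpi_columns) {
    col <- if (v %in% names(raw)) raw[[v]] else rep(NA_character_, n)
    if (v %in% c("herd_id", "calf_id")) {
      out[[v]] <- if (n) as.character(col) else character(0)
    } else if (v == "age_days") {
      x <- coerce_numeric(col, v)
      if (any(!is.na(x) & x != round(x)))
        warning("column 'age_days': non-integer ages rounded down", call. = FALSE)
      out[[v]] <- floor(x)
    } else {
      out[[v]] <- coerce_numeric(col, v)
    }
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  validate_calf_data(out)
  set_provenance(out, sprintf("read %d records from %s", n, path))
}

#' Write a calf dataset to CSV
#'
#' Writes the canonical columns in full (17 significant digit) precision so
#' that a write/read round trip reproduces every finite value bit-exactly and
#' preserves missingness (missing values become empty cells).
#'
#' @param ds a calf dataset (`data.frame` with the canonical columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_calf_data <- function(ds, path) {
  validate_calf_data(ds)
  cols <- intersect(c(ftpi_columns, "glob", "ftpi_status", "age_group"), names(ds))
  out <- ds[, cols, drop = FALSE]
  txt <- lapply(out, function(x) {
    if (is.numeric(x)) ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
    else ifelse(is.na(x), "", as.character(x))
  })
  txt <- as.data.frame(txt, stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(txt, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Restrict a dataset to an age window
#'
#' Retains calves whose age is known and lies inside the closed window
#' `[min_age, max_age]` days. Study cohorts of this kind exclude day-0/1
#' calves (incomplete colostral IgG absorption) and calves older than 6 days
#' (IgG catabolism and endogenous synthesis); the provenance attribute records
#' how many records each rule removed.
#'
#' @param ds a calf dataset.
#' @param min_age,max_age inclusive bounds, in days.
#' @return the filtered dataset, with updated provenance.
#' @export
apply_age_filter <- function(ds, min_age = 2, max_age = 6) {
  stopifnot(min_age <= max_age)
  age <- ds$age_days
  keep <- !is.na(age) & age >= min_age & age <= max_age
  n_missing <- sum(is.na(age))
  n_young <- sum(!is.na(age) & age < min_age)
  n_old <- sum(!is.na(age) & age > max_age)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(ds, "provenance")
  attr(out, "filter_counts") <- c(missing_age = n_missing, below_min = n_young,
                                  above_max = n_old, retained = sum(keep))
  set_provenance(out, sprintf(
    "age filter [%g, %g] d: removed %d missing-age, %d too young, %d too old; %d retained",
    min_age, max_age, n_missing, n_young, n_old, sum(keep)))
}

#' Derive globulin, FTPI status and age group
#'
#' Adds the analysis fields: calculated serum globulin
#' `glob = stp_ba - alb` (g/L, present only when both inputs are), the binary
#' reference classification `ftpi_status` (`TRUE` iff `igg_rid <
#' ftpi_threshold`, strict inequality, so a calf at exactly the threshold is
#' FTPI-negative), and the `age_group` factor used to stratify GGT analyses.
#'
#' @param ds a calf dataset.
#' @param ftpi_threshold IgG threshold in g/L below which a calf is classified
#'   as having failure of transfer of passive immunity. Default 10.0 g/L; 8.0
#'   g/L is the common alternative.
#' @param age_breaks two-element list of age ranges (days) defining the two
#'   analysis age groups.
#' @return `ds` with columns `glob`, `ftpi_status` and `age_group` appended.
#' @export
derive_fields <- function(ds, ftpi_threshold = 10,
                          age_breaks = list("2-3 d" = c(2, 3), "4-6 d" = c(4, 6))) {
  stopifnot(is.numeric(ftpi_threshold), length(ftpi_threshold) == 1L)
  out <- ds
  out$glob <- out$stp_ba - out$alb
  out$ftpi_status <- out$igg_rid < ftpi_threshold
  grp <- rep(NA_character_, nrow(out))
  for (g in names(age_breaks)) {
    rng <- age_breaks[[g]]
    grp[!is.na(out$age_days) & out$age_days >= rng[1] & out$age_days <= rng[2]] <- g
  }
  out$age_group <- factor(grp, levels = names(age_breaks))
  attr(out, "provenance") <- attr(ds, "provenance")
  attr(out, "ftpi_threshold") <- ftpi_threshold
  set_provenance(out, sprintf("derived glob, ftpi_status (IgG < %g g/L), age_group",
                              ftpi_threshold))
}

#' Per-variable descriptive statistics
#'
#' Complete-case descriptive summary of numeric variables: each variable is
#' summarised over its own non-missing subset (so `n` can differ between
#' variables, as it does when tests have different missingness). The standard
#' deviation uses the n-1 denominator; quartiles use linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param ds a calf dataset.
#' @param variables character vector of column names to summarise; defaults to
#'   all numeric measurement columns present.
#' @return a `data.frame` with one row per variable: `variable`, `n`, `mean`,
#'   `sd`, `q1`, `q3`. Variables with no observed values keep `n = 0` and `NA`
#'   statistics rather than erroring.
#' @export
describe_calves <- function(ds, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(c(ftpi_measurements, "glob"), names(ds))
  missing_vars <- setdiff(variables, names(ds))
  if (length(missing_vars))
    stop("unknown variable(s): ", paste(missing_vars, collapse = ", "))
  rows <- lapply(variables, function(v) {
    x <- ds[[v]]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(variable = v, n = 0L, mean = NA_real_, sd = NA_real_,
                        q1 = NA_real_, q3 = NA_real_))
    q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(variable = v, n = length(x), mean = mean(x),
               sd = stats::sd(x), q1 = q[1], q3 = q[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
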