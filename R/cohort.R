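.reference_md5 <- "f29c83d6e6c2d6498e01972c2de3937a"

#' Load the packaged regional-SUV reference table
#'
#' Per-patient regional analysis results for the 20 amyloid-positive
#' subjects of the reference cohort (15 wild-type, 5 variant transthyretin
#' amyloidosis), ordered by ascending total cardiac SUV: genotype, total
#' cardiac SUV, COV, and summed SUVs of the basal (segments 1-12), apical
#' (13-17), septal (2, 3, 8, 9, 14) and lateral (5, 6, 11, 12, 16) regions.
#' The file is checksummed on load and its internal consistency (basal +
#' apical = total within 2-decimal rounding) is validated.
#'
#' @return data.frame with 20 rows, columns `genotype`
#'   (`"wt"`/`"v"`), `total_cardiac_suv`, `cov`, `summed_basal`,
#'   `summed_apical`, `summed_septal`, `summed_lateral`.
#' @export
load_regional_suv_reference <- function() {
  path <- system.file("extdata", "regional_suv_reference.csv",
                      package = "pypquant", mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .reference_md5)
    stop("packaged regional-SUV table failed its checksum")
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(d) != 20L) stop("fixture must have 20 rows")
  if (sum(d$genotype == "wt") != 15L || sum(d$genotype == "v") != 5L)
    stop("fixture must contain 15 wild-type and 5 variant records")
  if (is.unsorted(d$total_cardiac_suv))
    stop("fixture must be ordered by ascending total cardiac SUV")
  err <- abs(d$summed_basal + d$summed_apical - d$total_cardiac_suv)
  if (any(err > 0.02))
    stop("basal + apical does not match total cardiac SUV within 0.02")
  d
}

#' Derive %DS and %BA for a regional-SUV table
#'
#' Adds `pct_ds = (septal - lateral) / total * 100` and
#' `pct_ba = (basal - apical) / total * 100` columns.
#'
#' @param fix data.frame as returned by [load_regional_suv_reference()].
#' @return The table with `pct_ds` and `pct_ba` appended.
#' @export
derive_reference_indices <- function(fix) {
  need <- c("total_cardiac_suv", "summed_basal", "summed_apical",
            "summed_septal", "summed_lateral")
  if (!all(need %in% names(fix))) stop("missing required columns")
  fix$pct_ds <- (fix$summed_septal - fix$summed_lateral) /
    fix$total_cardiac_suv * 100
  fix$pct_ba <- (fix$summed_basal - fix$summed_apical) /
    fix$total_cardiac_suv * 100
  fix
}

#' Correlations of heterogeneity indices with total cardiac SUV
#'
#' For each genotype subset (combined, wild-type only, variant only),
#' Pearson correlations of COV, %DS and %BA against total cardiac SUV.
#'
#' @param cohort a regional-SUV table with `genotype`, `cov`, `pct_ds`,
#'   `pct_ba` and `total_cardiac_suv` columns (see
#'   [derive_reference_indices()]).
#' @return data.frame with columns `subset`, `index`, `r`, `p`, `n`.
#' @export
burden_correlations <- function(cohort) {
  subsets <- list(all = cohort,
                  wt = cohort[cohort$genotype == "wt", ],
                  v = cohort[cohort$genotype == "v", ])
  out <- list()
  for (s in names(subsets)) {
    d <- subsets[[s]]
    if (nrow(d) < 3) stop("subset '", s, "' has fewer than 3 rows")
    for (ix in c("cov", "pct_ds", "pct_ba")) {
      ct <- pearson(d[[ix]], d$total_cardiac_suv)
      out[[length(out) + 1L]] <- data.frame(
        subset = s, index = ix, r = ct$r, p = ct$p, n = ct$n)
    }
  }
  do.call(rbind, out)
}

#' Read / write a cohort table as CSV
#'
#' Comma-separated, UTF-8, header row, `.` decimal separator, empty fields
#' for missing values; numeric precision is preserved.
#'
#' @param cohort data.frame.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
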