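#' Read and validate long-format cohort count data
#'
#' Cohort count tables record, for every assay population and sampling day,
#' the number of individuals counted in each stage (eggs, immatures, adults)
#' from the photographs. One row per assay population x sampling day.
#'
#' @param path path to a CSV file with columns `assay_id`, `colony_id`,
#'   `cultivar`, `cohort_type` (`"egg"` or `"adult"`), `day`, `eggs`,
#'   `immatures`, `adults`.
#' @return A validated `data.frame` of cohort counts.
#' @seealso [simulate_experiment()] to generate such a table,
#'   [derive_maturation_intervals()] and friends to reduce it to the three
#'   analysis datasets.
#' @export
read_cohort_counts <- function(path) {
  counts <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort_counts(counts)
}

#' @rdname read_cohort_counts
#' @param counts a data frame of cohort counts.
#' @export
validate_cohort_counts <- function(counts) {
  missing_cols <- setdiff(.count_cols, names(counts))
  if (length(missing_cols))
    stop("cohort count data is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- c("day", "eggs", "immatures", "adults")
  for (col in num) {
    if (!is.numeric(counts[[col]]))
      stop("column '", col, "' must be numeric")
    bad <- which(!is.finite(counts[[col]]) | counts[[col]] < 0)
    if (length(bad))
      stop("column '", col, "' has missing/negative values at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!all(counts$cohort_type %in% c("egg", "adult")))
    stop("cohort_type must be 'egg' or 'adult'")
  if (length(unique(counts$cultivar)) > 2)
    stop("more than two cultivar levels present")
  co <- unique(counts[, c("assay_id", "colony_id")])
  if (anyDuplicated(co$assay_id))
    stop("an assay population maps to more than one colony")
  cu <- unique(counts[, c("colony_id", "cultivar")])
  if (anyDuplicated(cu$colony_id))
    stop("a colony maps to more than one cultivar")
  counts[order(counts$assay_id, counts$day), , drop = FALSE]
}

# split validated counts into per-assay blocks with a checked day grid
# (strictly increasing, equally spaced)
split_assays <- function(counts) {
  out <- split(counts, counts$assay_id)
  lapply(out, function(a) {
    a <- a[order(a$day), , drop = FALSE]
    d <- a$day
    if (length(d) < 2 || any(diff(d) <= 0) ||
        length(unique(diff(d))) != 1)
      stop("assay ", a$assay_id[1],
           ": sampling days must be strictly increasing and equally spaced")
    a
  })
}
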