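#' Common-garden experiment design
#'
#' Describes the hierarchical design of a common-garden cohort experiment:
#' source cultivars, sample colonies, assay populations (cohorts) per colony,
#' cohort sizes, and the photographic sampling schedule. The default mirrors
#' a design with 11 sample colonies (8 founded from Zinfandel vineyards, 3
#' from Chardonnay), 2 egg cohorts of 10 eggs and 2 adult cohorts of 5 mated
#' females per colony, sampled every 2 days for 12 days.
#'
#' @param colonies data frame with columns `colony_id` and `cultivar`
#'   (exactly two cultivar levels). Default: 8 Zinfandel + 3 Chardonnay.
#' @param egg_cohorts,adult_cohorts number of egg-initiated and
#'   adult-initiated assay populations per colony.
#' @param egg_cohort_size number of eggs founding an egg cohort.
#' @param adult_cohort_size number of mated females founding an adult cohort.
#' @param sample_interval days between photographic samples.
#' @param study_length total length of the assay in days; must be a multiple
#'   of `sample_interval`.
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' sampling_days(d)   # 0 2 4 6 8 10 12
#' @export
experiment_design <- function(colonies = default_colonies(),
                              egg_cohorts = 2,
                              adult_cohorts = 2,
                              egg_cohort_size = 10,
                              adult_cohort_size = 5,
                              sample_interval = 2,
                              study_length = 12) {
  colonies <- as.data.frame(colonies)
  stopifnot(all(c("colony_id", "cultivar") %in% names(colonies)),
            !anyDuplicated(colonies$colony_id),
            egg_cohorts >= 0, adult_cohorts >= 0,
            egg_cohort_size >= 1, adult_cohort_size >= 1,
            sample_interval > 0, study_length > 0)
  if (study_length %% sample_interval != 0)
    stop("study_length must be a multiple of sample_interval")
  lev <- unique(as.character(colonies$cultivar))
  if (length(lev) > 2)
    stop("cultivar must have at most two levels, got: ",
         paste(lev, collapse = ", "))
  colonies$colony_id <- as.character(colonies$colony_id)
  colonies$cultivar <- as.character(colonies$cultivar)
  structure(list(colonies = colonies,
                 egg_cohorts = egg_cohorts,
                 adult_cohorts = adult_cohorts,
                 egg_cohort_size = egg_cohort_size,
                 adult_cohort_size = adult_cohort_size,
                 sample_interval = sample_interval,
                 study_length = study_length),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @export
default_colonies <- function() {
  data.frame(colony_id = c(sprintf("Z%02d", 1:8), sprintf("C%02d", 1:3)),
             cultivar = rep(c("Zinfandel", "Chardonnay"), c(8L, 3L)),
             stringsAsFactors = FALSE)
}

#' @rdname experiment_design
#' @param design an `experiment_design` object.
#' @export
sampling_days <- function(design) {
  seq(0L, design$study_length, by = design$sample_interval)
}

#' @export
print.experiment_design <- function(x, ...) {
  tab <- table(x$colonies$cultivar)
  cat("Common-garden experiment design\n")
  cat("  colonies: ", nrow(x$colonies), " (",
      paste(sprintf("%d %s", tab, names(tab)), collapse = ", "), ")\n", sep = "")
  cat("  per colony:", x$egg_cohorts, "egg cohorts of", x$egg_cohort_size,
      "eggs;", x$adult_cohorts, "adult cohorts of", x$adult_cohort_size,
      "females\n")
  cat("  sampling: every", x$sample_interval, "days for", x$study_length,
      "days (", length(sampling_days(x)), "occasions )\n")
  invisible(x)
}
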