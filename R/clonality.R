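# Clonal/subclonal decomposition of VAF distributions, per-doubling mutation
# rates, and the group-comparison statistics used on cohort mutation sets.

#' Split mutations into clonal and subclonal by VAF clustering
#'
#' One-dimensional two-centre k-means on the VAFs (Lloyd iterations from a
#' deterministic initialisation at the 25th/75th VAF percentiles); the border
#' is the midpoint of the two final centres and the upper cluster is labelled
#' clonal. Samples with fewer than `min_per_class` mutations in either
#' category are flagged as excluded (`included = FALSE`).
#'
#' @param vafs numeric vector of variant allele frequencies in \[0, 1\].
#' @param min_per_class inclusion threshold per category (default 300).
#' @return object of class `clonality_split`: `border_vaf`, `centers`,
#'   `clonal_count`, `subclonal_count`, `included`, and per-mutation `labels`
#'   (`"clonal"`/`"subclonal"`).
#' @export
split_clonal_subclonal <- function(vafs, min_per_class = 300L) {
  if (any(vafs < 0 | vafs > 1, na.rm = TRUE)) stop("VAFs must lie in [0, 1]")
  vafs <- vafs[!is.na(vafs)]
  if (length(unique(vafs)) < 2L) {
    stop("need at least 2 distinct VAF values to split")
  }
  init <- stats::quantile(vafs, c(0.25, 0.75), names = FALSE)
  if (init[1] == init[2]) init <- range(vafs)
  km <- stats::kmeans(vafs, centers = matrix(init, ncol = 1),
                      algorithm = "Lloyd", iter.max = 1000L)
  centers <- sort(as.numeric(km$centers))
  border <- mean(centers)
  labels <- ifelse(vafs >= border, "clonal", "subclonal")
  n_clonal <- sum(labels == "clonal")
  n_sub <- length(labels) - n_clonal
  structure(list(border_vaf = border, centers = centers,
                 clonal_count = n_clonal, subclonal_count = n_sub,
                 included = n_clonal >= min_per_class &&
                   n_sub >= min_per_class,
                 labels = labels),
            class = "clonality_split")
}

#' @export
print.clonality_split <- function(x, ...) {
  cat(sprintf(
    "<clonality_split: border VAF %.3f, %d clonal / %d subclonal%s>\n",
    x$border_vaf, x$clonal_count, x$subclonal_count,
    if (x$included) "" else " (excluded: a category is below threshold)"))
  invisible(x)
}

#' Mutation rate per population doubling
#'
#' `doublings = days * 24 / doubling_time_hours`; the rate is the mutation
#' total divided by the doublings, and the per-megabase rate additionally by
#' the genome size.
#'
#' @param n_mutations total mutation count (>= 0).
#' @param days days in culture.
#' @param doubling_time_hours mean population doubling time in hours.
#' @param genome_mb genome size in megabases for the per-Mb rate.
#' @return object of class `rate_result` with `population_doublings`,
#'   `rate_per_doubling` and `rate_per_mb`.
#' @export
rate_per_doubling <- function(n_mutations, days, doubling_time_hours,
                              genome_mb = 3100) {
  if (days <= 0 || doubling_time_hours <= 0 || genome_mb <= 0) {
    stop("days, doubling time and genome size must be positive")
  }
  if (any(n_mutations < 0)) stop("negative mutation count")
  doublings <- days * 24 / doubling_time_hours
  structure(list(total_mutations = n_mutations,
                 days = days,
                 doubling_time_hours = doubling_time_hours,
                 population_doublings = doublings,
                 rate_per_doubling = n_mutations / doublings,
                 rate_per_mb = n_mutations / doublings / genome_mb),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf(
    "<rate_result: %g mutations over %.1f doublings -> %.3f per doubling (%.3g per Mb per doubling)>\n",
    sum(x$total_mutations), x$population_doublings,
    mean(x$rate_per_doubling), mean(x$rate_per_mb)))
  invisible(x)
}

#' Unpaired two-sided t-test between groups
#'
#' Pooled-variance (equal-variance) form by default, matching the group
#' comparisons used throughout; Welch available behind `var_equal = FALSE`
#' and the choice is recorded in the output.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @param var_equal use the pooled-variance form (default `TRUE`).
#' @return list: `t`, `p`, `means`, `sds`, `sems`, `var_equal`.
#' @export
ttest_unpaired <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("need at least 2 values per group")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       means = c(mean(group_a), mean(group_b)),
       sds = c(stats::sd(group_a), stats::sd(group_b)),
       sems = c(stats::sd(group_a) / sqrt(length(group_a)),
                stats::sd(group_b) / sqrt(length(group_b))),
       var_equal = var_equal)
}

#' Paired two-sided t-test
#'
#' @param a,b aligned numeric vectors (pairs) with at least 2 pairs.
#' @return list with `t` and `p`.
#' @export
ttest_paired <- function(a, b) {
  if (length(a) != length(b)) stop("paired inputs must be aligned")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = 0, p = 1))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Compare signature contributions between clonal and subclonal spectra
#'
#' Takes per-sample signature fits for the clonal and the subclonal
#' compartment (named lists of exposure vectors from the same reference set),
#' converts exposures to relative contributions per compartment, and runs a
#' paired two-sided t-test per signature. Samples missing either compartment
#' are excluded (and reported).
#'
#' @param clonal_fits,subclonal_fits named lists (by sample) of exposure
#'   vectors or `signature_fit` objects.
#' @return data frame: signature, mean_clonal, mean_subclonal, t, p; the
#'   excluded samples are in the `excluded` attribute.
#' @export
compare_clonal_subclonal_exposures <- function(clonal_fits, subclonal_fits) {
  as_exp <- function(x) if (inherits(x, "signature_fit")) x$exposures else x
  clonal_fits <- lapply(clonal_fits, as_exp)
  subclonal_fits <- lapply(subclonal_fits, as_exp)
  shared <- intersect(names(clonal_fits), names(subclonal_fits))
  excluded <- setdiff(union(names(clonal_fits), names(subclonal_fits)),
                      shared)
  if (length(shared) < 2) stop("need at least 2 samples with both fits")
  signames <- names(clonal_fits[[shared[1]]])
  rel <- function(v) v / sum(v)
  cm <- vapply(clonal_fits[shared], rel, numeric(length(signames)))
  sm <- vapply(subclonal_fits[shared], rel, numeric(length(signames)))
  out <- data.frame(signature = signames,
                    mean_clonal = rowMeans(cm),
                    mean_subclonal = rowMeans(sm),
                    t = NA_real_, p = NA_real_)
  for (r in seq_along(signames)) {
    tt <- ttest_paired(cm[r, ], sm[r, ])
    out$t[r] <- tt$t
    out$p[r] <- tt$p
  }
  attr(out, "excluded") <- excluded
  out
}
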