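#' Flowering interval for one colour form
#'
#' A form's flowering season, from the first day any plant opened a flower
#' to the last day any flower remained open. Both endpoints are counted as
#' flowering days (inclusive convention), which is how the phenological
#' overlap proportions are defined throughout the package.
#'
#' @param form Form label, e.g. `"white"` or `"pink"`.
#' @param first_day,last_day First and last flowering day (`Date` or
#'   ISO-8601 string).
#' @return A `flowering_interval` object (named list with `form`,
#'   `first_day`, `last_day`).
#' @export
#' @examples
#' flowering_interval("white", "2016-07-24", "2016-09-09")
flowering_interval <- function(form, first_day, last_day) {
  first_day <- ib_as_date(first_day, "first_day")
  last_day <- ib_as_date(last_day, "last_day")
  if (last_day < first_day) {
    ib_stop(sprintf("flowering interval for '%s' is reversed (%s > %s)",
                    form, first_day, last_day),
            "isobarrier_invalid_input")
  }
  structure(list(form = as.character(form),
                 first_day = first_day, last_day = last_day),
            class = "flowering_interval")
}

#' @export
print.flowering_interval <- function(x, ...) {
  cat(sprintf("<flowering_interval> %s: %s to %s (%d days)\n",
              x$form, x$first_day, x$last_day, interval_days(x)))
  invisible(x)
}

#' Inclusive duration of a flowering interval in days
#'
#' @param x A [flowering_interval()].
#' @return Integer day count including both endpoints.
#' @export
interval_days <- function(x) {
  stopifnot(inherits(x, "flowering_interval"))
  as.integer(x$last_day - x$first_day) + 1L
}

#' Shared and unshared flowering days between two forms
#'
#' Counts the days on which both forms flower (the intersection of the two
#' intervals, inclusive of endpoints) and the days on which only the focal
#' form `a` flowers. These are the S and U inputs to [phenology_ri()] from
#' the perspective of form `a` as maternal parent.
#'
#' @param a,b [flowering_interval()] objects; `a` is the focal (maternal)
#'   form.
#' @return Named list with integer `shared` and `unshared` day counts;
#'   `shared + unshared` equals `interval_days(a)`.
#' @export
#' @examples
#' w <- flowering_interval("white", "2016-07-24", "2016-09-09")
#' p <- flowering_interval("pink", "2016-07-31", "2016-09-14")
#' overlap_days(w, p)  # shared 41, unshared 7
overlap_days <- function(a, b) {
  stopifnot(inherits(a, "flowering_interval"), inherits(b, "flowering_interval"))
  lo <- max(a$first_day, b$first_day)
  hi <- min(a$last_day, b$last_day)
  shared <- max(0L, as.integer(hi - lo) + 1L)
  list(shared = shared, unshared = interval_days(a) - shared)
}

#' Phenological reproductive isolation
#'
#' RI from flowering-time overlap: `1 - S/(S + U)` where S is the shared
#' and U the unshared flowering time of the maternal form. Zero when the
#' forms co-flower completely, one when they never overlap. Note the
#' formula differs from [pairwise_ri()] (no factor of 2): complete overlap
#' means no phenological barrier at all, not random mating.
#'
#' @param shared,unshared Nonnegative shared/unshared flowering time (days
#'   or proportions; only the ratio matters).
#' @return RI in \[0, 1\].
#' @export
#' @examples
#' phenology_ri(41, 7)  # 0.1458..., the white form's barrier
phenology_ri <- function(shared, unshared) {
  if (any(shared < 0) || any(unshared < 0)) {
    ib_stop("shared and unshared flowering time must be nonnegative",
            "isobarrier_invalid_input")
  }
  tot <- shared + unshared
  if (any(tot == 0)) {
    ib_stop("RI undefined: shared and unshared flowering time both zero",
            "isobarrier_undefined_ri")
  }
  1 - shared / tot
}

#' Pairwise reproductive isolation from conspecific/heterospecific success
#'
#' The RI index `1 - 2 * H / (H + C)`, where C is the conspecific
#' (intraform) and H the heterospecific (interform) success measure for
#' one maternal direction. Ranges over \[-1, 1\]: 1 means complete
#' isolation (no heterospecific success), 0 random mating (C = H), and
#' negative values a heterospecific advantage. C and H must be measured
#' in the same units (counts, means, rates); the index is invariant to
#' rescaling both by a common positive factor.
#'
#' @param conspecific,heterospecific Nonnegative success measures, same
#'   units; vectors are recycled elementwise.
#' @return RI in \[-1, 1\].
#' @export
#' @examples
#' pairwise_ri(64, 20)            # pollinator barrier, pink maternal: 0.5238
#' pairwise_ri(118.93, 125.62)    # pollen tubes, white maternal: -0.027
pairwise_ri <- function(conspecific, heterospecific) {
  if (any(conspecific < 0) || any(heterospecific < 0)) {
    ib_stop("success measures must be nonnegative", "isobarrier_invalid_input")
  }
  tot <- conspecific + heterospecific
  if (any(tot == 0)) {
    ib_stop("RI undefined: conspecific and heterospecific success both zero",
            "isobarrier_undefined_ri")
  }
  1 - 2 * heterospecific / tot
}

#' Directional asymmetry of a barrier
#'
#' Absolute difference between a barrier's RI in the two crossing
#' directions, computed on unrounded inputs.
#'
#' @param ri_dir1,ri_dir2 RI of the same barrier for each maternal
#'   direction.
#' @return Nonnegative asymmetry value.
#' @export
#' @examples
#' ri_asymmetry(phenology_ri(41, 7), phenology_ri(41, 5))  # 0.037 -> 0.04
ri_asymmetry <- function(ri_dir1, ri_dir2) {
  if (any(!is.finite(ri_dir1)) || any(!is.finite(ri_dir2))) {
    ib_stop("both RI values must be finite", "isobarrier_invalid_input")
  }
  abs(ri_dir1 - ri_dir2)
}

#' Record a conspecific/heterospecific success pair for one barrier
#'
#' Keeps the co-measured pair (same units, same maternal direction) in one
#' record, together with the barrier name. `maternal_form` identifies the
#' direction: C is conspecific success *into* that form, H heterospecific
#' success into it.
#'
#' @param barrier Barrier name (free text, e.g. `"pollinator"`).
#' @param maternal_form Maternal form label.
#' @param conspecific,heterospecific Nonnegative success measures (counts,
#'   means or proportions, co-measured).
#' @param n Optional sample size behind the pair.
#' @return A one-row tibble of class `success_pair`.
#' @export
success_pair <- function(barrier, maternal_form, conspecific, heterospecific,
                         n = NA_integer_) {
  if (conspecific < 0 || heterospecific < 0) {
    ib_stop("success measures must be nonnegative", "isobarrier_invalid_input")
  }
  if (conspecific == 0 && heterospecific == 0) {
    ib_stop("success pair with C = H = 0 carries no information (RI undefined)",
            "isobarrier_undefined_ri")
  }
  out <- tibble::tibble(
    barrier = as.character(barrier),
    maternal_form = as.character(maternal_form),
    conspecific = as.numeric(conspecific),
    heterospecific = as.numeric(heterospecific),
    n = as.integer(n)
  )
  class(out) <- c("success_pair", class(out))
  out
}

#' Barrier estimate: RI for one barrier and direction, optionally with a
#' bootstrap interval
#'
#' @param pair A [success_pair()].
#' @param ci_low,ci_high Optional bootstrap interval bounds (see
#'   [ri_bootstrap_ci()]).
#' @return One-row tibble: barrier, maternal_form, conspecific,
#'   heterospecific, n, ri, ci_low, ci_high.
#' @export
barrier_estimate <- function(pair, ci_low = NA_real_, ci_high = NA_real_) {
  stopifnot(inherits(pair, "success_pair"))
  dplyr::mutate(tibble::as_tibble(pair),
                ri = pairwise_ri(.data$conspecific, .data$heterospecific),
                ci_low = ci_low, ci_high = ci_high)
}

#' Percentile bootstrap interval for a pairwise RI estimate
#'
#' Resamples the underlying per-trial observations within each class
#' (conspecific and heterospecific outcomes), recomputes the class means
#' and the RI index for each resample, and returns the percentile
#' interval. Degenerate resamples where both class means are zero carry no
#' information and are dropped with a warning.
#'
#' @param conspecific_obs,heterospecific_obs Numeric vectors of per-trial
#'   outcomes (e.g. tube counts, 0/1 fruit set); at least 2 each.
#' @param B Number of bootstrap resamples (>= 100).
#' @param conf Interval coverage (default 0.95).
#' @param seed Optional integer seed for reproducibility.
#' @return Named list: `estimate`, `low`, `high`, `B_used` (resamples
#'   retained after dropping degenerate ones).
#' @export
#' @examples
#' ri_bootstrap_ci(rpois(30, 100), rpois(30, 80), B = 500, seed = 1)
ri_bootstrap_ci <- function(conspecific_obs, heterospecific_obs,
                            B = 2000, conf = 0.95, seed = NULL) {
  if (length(conspecific_obs) < 2 || length(heterospecific_obs) < 2) {
    ib_stop("need at least 2 observations per class to bootstrap",
            "isobarrier_invalid_input")
  }
  if (B < 100) {
    ib_stop("B must be at least 100", "isobarrier_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  nc <- length(conspecific_obs)
  nh <- length(heterospecific_obs)
  cm <- colMeans(matrix(sample(conspecific_obs, nc * B, replace = TRUE), nc))
  hm <- colMeans(matrix(sample(heterospecific_obs, nh * B, replace = TRUE), nh))
  ok <- (cm + hm) > 0
  if (!all(ok)) {
    warning(sprintf("%d degenerate bootstrap resamples (C = H = 0) dropped",
                    sum(!ok)))
  }
  ris <- 1 - 2 * hm[ok] / (cm[ok] + hm[ok])
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(ris, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(
    estimate = pairwise_ri(mean(conspecific_obs), mean(heterospecific_obs)),
    low = qs[1], high = qs[2], B_used = sum(ok)
  )
}
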