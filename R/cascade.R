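#' Relative heterospecific success of a barrier
#'
#' Normalises a success pair to h = H/C, the heterospecific success per
#' unit of conspecific success. h = 0 is an absolute barrier, h = 1 no
#' barrier, h > 1 a heterospecific advantage (anti-isolation). This is the
#' per-stage quantity the sequential cascade multiplies.
#'
#' @param conspecific,heterospecific Success measures; `conspecific` must
#'   be positive.
#' @return h = H/C, nonnegative.
#' @export
#' @examples
#' relative_success(370, 20)  # 0.054: pollinators rarely cross forms
relative_success <- function(conspecific, heterospecific) {
  if (any(conspecific <= 0)) {
    ib_stop(paste("conspecific success must be positive to normalise;",
                  "for C = 0 use pairwise_ri() directly"),
            "isobarrier_invalid_input")
  }
  if (any(heterospecific < 0)) {
    ib_stop("heterospecific success must be nonnegative",
            "isobarrier_invalid_input")
  }
  heterospecific / conspecific
}

#' Invert a published RI value to relative success
#'
#' When only a barrier's published RI is available (no raw rates), the
#' relative success it implies is h = (1 - RI)/(1 + RI), the inverse of
#' `RI = 1 - 2h/(1 + h)`. `pairwise_ri(1, h_from_ri(ri))` returns `ri`
#' exactly.
#'
#' @param ri RI value in (-1, 1\].
#' @return Relative success h >= 0.
#' @export
#' @examples
#' h_from_ri(0.39)  # 0.4388
h_from_ri <- function(ri) {
  if (any(ri <= -1) || any(ri > 1)) {
    ib_stop("RI must lie in (-1, 1] to invert", "isobarrier_invalid_input")
  }
  (1 - ri) / (1 + ri)
}

#' Assemble a sequential barrier cascade for one maternal direction
#'
#' Orders a direction's barriers in life-history sequence after the
#' phenological stage. The cascade evaluates cumulative RI under two
#' assumptions: no heterospecific mating occurs outside the co-flowering
#' period (H_U = 0), and conspecific success is unaffected by
#' co-flowering (C_S = C_U, normalised to 1). Stage 1 is phenology alone;
#' stage i adds the (i-1)-th post-phenology barrier.
#'
#' @param maternal_form Maternal form label.
#' @param shared,unshared Shared/unshared flowering time of the maternal
#'   form (days or proportions; normalised internally to S + U = 1).
#' @param barriers Data frame with columns `barrier`, `conspecific`,
#'   `heterospecific` in the order the barriers act (e.g. pollinator
#'   foraging, pollinia-pistil, fruit production, seed development). All
#'   `conspecific` values must be positive.
#' @return A `barrier_cascade` object.
#' @export
#' @examples
#' barrier_cascade("white", shared = 41, unshared = 7,
#'   barriers = data.frame(
#'     barrier = c("pollinator", "pollen_tube"),
#'     conspecific = c(370, 118.93),
#'     heterospecific = c(20, 125.62)))
barrier_cascade <- function(maternal_form, shared, unshared, barriers) {
  if (shared < 0 || unshared < 0 || shared + unshared == 0) {
    ib_stop("invalid phenology: need shared >= 0, unshared >= 0, S + U > 0",
            "isobarrier_invalid_input")
  }
  barriers <- tibble::as_tibble(barriers)
  need <- c("barrier", "conspecific", "heterospecific")
  if (!all(need %in% names(barriers))) {
    ib_stop(sprintf("barriers must have columns: %s",
                    paste(need, collapse = ", ")),
            "isobarrier_invalid_input")
  }
  h <- relative_success(barriers$conspecific, barriers$heterospecific)
  structure(list(
    maternal_form = as.character(maternal_form),
    S = shared / (shared + unshared),
    U = unshared / (shared + unshared),
    barriers = barriers,
    h = stats::setNames(h, barriers$barrier)
  ), class = "barrier_cascade")
}

#' @export
print.barrier_cascade <- function(x, ...) {
  cat(sprintf("<barrier_cascade> maternal form %s: S = %.4f, stages:\n",
              x$maternal_form, x$S))
  cat(sprintf("  1. phenology (RI = %.4f)\n", x$U))
  for (i in seq_along(x$h)) {
    cat(sprintf("  %d. %s (h = %.4f)\n", i + 1, names(x$h)[i], x$h[i]))
  }
  invisible(x)
}

#' Cumulative reproductive isolation through stage i
#'
#' Stage 1 is the phenological barrier alone, `1 - S/(S + U) = U`. Later
#' stages compose the relative successes multiplicatively: with
#' heterospecific success confined to the shared period and conspecific
#' success normalised to 1 in both periods, the total-RI formula
#' `1 - 2(S*H_S + U*H_U) / ((S*H_S + U*H_U) + (S*C_S + U*C_U))`
#' reduces to `1 - 2*S*prod(h) / (S*prod(h) + 1)` over the first i - 1
#' post-phenology barriers.
#'
#' @param cascade A [barrier_cascade()].
#' @param i Stage index, 1 (phenology) to `nrow(cascade$barriers) + 1`
#'   (all barriers).
#' @return Cumulative RI at stage i.
#' @export
cumulative_ri <- function(cascade, i) {
  stopifnot(inherits(cascade, "barrier_cascade"))
  n_stages <- length(cascade$h) + 1L
  if (i < 1 || i > n_stages) {
    ib_stop(sprintf("stage index %d out of range [1, %d]", i, n_stages),
            "isobarrier_invalid_input")
  }
  if (i == 1) return(cascade$U)
  hprod <- prod(cascade$h[seq_len(i - 1)])
  sh <- cascade$S * hprod
  1 - 2 * sh / (sh + 1)
}

#' Per-barrier contributions to total reproductive isolation
#'
#' Computes the cumulative RI at every stage, each barrier's absolute
#' contribution (the increment over the previous stage, which telescopes
#' so that the contributions sum exactly to total RI) and its relative
#' contribution (absolute contribution divided by total RI). A stage
#' acting after strong earlier barriers can contribute little however
#' strong it is in isolation; a stage with h > 1 contributes negatively.
#'
#' @param cascade A [barrier_cascade()].
#' @return A `cascade_result`: tibble with columns `stage`, `barrier`,
#'   `cumulative_ri`, `abs_contrib`, `rel_contrib`, plus attributes
#'   `total_ri` and `maternal_form`. `rel_contrib` is NA (with a warning)
#'   when total RI is 0.
#' @export
#' @examples
#' casc <- barrier_cascade("white", 41, 7,
#'   data.frame(barrier = "pollinator", conspecific = 370,
#'              heterospecific = 20))
#' cascade_contributions(casc)
cascade_contributions <- function(cascade) {
  stopifnot(inherits(cascade, "barrier_cascade"))
  n_stages <- length(cascade$h) + 1L
  cum <- vapply(seq_len(n_stages), function(i) cumulative_ri(cascade, i),
                numeric(1))
  ac <- diff(c(0, cum))
  total <- cum[n_stages]
  if (total == 0) {
    warning("total RI is 0; relative contributions undefined")
    rc <- rep(NA_real_, n_stages)
  } else {
    rc <- ac / total
  }
  out <- tibble::tibble(
    stage = seq_len(n_stages),
    barrier = c("phenology", names(cascade$h)),
    cumulative_ri = cum,
    abs_contrib = ac,
    rel_contrib = rc
  )
  attr(out, "total_ri") <- total
  attr(out, "maternal_form") <- cascade$maternal_form
  class(out) <- c("cascade_result", class(out))
  out
}

#' Total reproductive isolation of a cascade
#'
#' @param cascade A [barrier_cascade()].
#' @return Cumulative RI through all stages.
#' @export
total_ri <- function(cascade) {
  cumulative_ri(cascade, length(cascade$h) + 1L)
}

#' Compare the two crossing directions of a study
#'
#' Evaluates both maternal directions' cascades (which must list the same
#' barriers in the same order) and the per-stage asymmetry of their
#' cumulative RI.
#'
#' @param cascade_1,cascade_2 [barrier_cascade()] objects for the two
#'   maternal directions.
#' @return Named list: `results` (one [cascade_contributions()] per
#'   direction, named by maternal form), `totals` (named numeric), and
#'   `asymmetry` tibble with per-stage `|difference|` of cumulative RI.
#' @export
compare_directions <- function(cascade_1, cascade_2) {
  stopifnot(inherits(cascade_1, "barrier_cascade"),
            inherits(cascade_2, "barrier_cascade"))
  if (!identical(cascade_1$barriers$barrier, cascade_2$barriers$barrier)) {
    ib_stop("cascades must list the same barriers in the same order",
            "isobarrier_invalid_input")
  }
  r1 <- cascade_contributions(cascade_1)
  r2 <- cascade_contributions(cascade_2)
  res <- stats::setNames(list(r1, r2),
                         c(cascade_1$maternal_form, cascade_2$maternal_form))
  asym <- tibble::tibble(
    stage = r1$stage,
    barrier = r1$barrier,
    asymmetry = abs(r1$cumulative_ri - r2$cumulative_ri)
  )
  list(
    results = res,
    totals = stats::setNames(
      c(attr(r1, "total_ri"), attr(r2, "total_ri")),
      c(cascade_1$maternal_form, cascade_2$maternal_form)
    ),
    asymmetry = asym
  )
}
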