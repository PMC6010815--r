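#' Tabulate plant-to-plant foraging transitions
#'
#' Turns ordered foraging logs into a table of transitions between colour
#' forms. A transition is a move between two distinct plants: consecutive
#' records of the same plant (a bee probing several flowers on one
#' inflorescence) are collapsed first. Transitions are counted within each
#' foraging bout and never bridge bouts; bouts with fewer than two
#' distinct plants yield none.
#'
#' @param log Data frame with columns `forager_id`, `species`,
#'   `visit_index`, `plant_id`, `form`, and optionally `bout_id` (defaults
#'   to one bout per forager).
#' @param forms Character vector of the two admissible form labels.
#' @return A `transition_table`: tibble with columns `from`, `to`, `count`
#'   covering all four ordered form pairs, with attributes `per_forager`
#'   (same shape plus `forager_id`, `species`) and `forms`.
#' @export
#' @examples
#' log <- data.frame(forager_id = "b1", species = "Apis", visit_index = 1:3,
#'                   plant_id = c("p1", "p2", "p3"),
#'                   form = c("white", "white", "pink"))
#' tabulate_transitions(log)
tabulate_transitions <- function(log, forms = c("white", "pink")) {
  log <- tibble::as_tibble(log)
  need <- c("forager_id", "species", "visit_index", "plant_id", "form")
  if (!all(need %in% names(log))) {
    ib_stop(sprintf("foraging log must have columns: %s",
                    paste(need, collapse = ", ")),
            "isobarrier_invalid_input")
  }
  if (length(forms) != 2) {
    ib_stop("exactly two form labels must be declared",
            "isobarrier_invalid_input")
  }
  bad <- setdiff(unique(log$form), forms)
  if (length(bad) > 0) {
    ib_stop(sprintf("unknown form label(s): %s", paste(bad, collapse = ", ")),
            "isobarrier_invalid_input")
  }
  if (!"bout_id" %in% names(log)) log$bout_id <- log$forager_id

  pair_grid <- tidyr_expand_forms(forms)
  per <- log |>
    dplyr::arrange(.data$forager_id, .data$bout_id, .data$visit_index) |>
    dplyr::group_by(.data$forager_id, .data$species, .data$bout_id) |>
    dplyr::group_modify(function(d, key) bout_transitions(d, forms)) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$forager_id, .data$species, .data$from, .data$to) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  counts <- dplyr::left_join(pair_grid,
                             dplyr::group_by(per, .data$from, .data$to) |>
                               dplyr::summarise(count = sum(.data$count),
                                                .groups = "drop"),
                             by = c("from", "to")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L, .data$count))

  structure(counts, per_forager = per, forms = forms,
            class = c("transition_table", class(counts)))
}

# All four ordered (from, to) form pairs.
tidyr_expand_forms <- function(forms) {
  tibble::tibble(from = rep(forms, each = 2), to = rep(forms, 2))
}

# Transitions within one bout: collapse repeat visits to the same plant,
# then count consecutive (from, to) form pairs.
bout_transitions <- function(d, forms) {
  keep <- c(TRUE, d$plant_id[-1] != d$plant_id[-nrow(d)])
  f <- d$form[keep]
  if (length(f) < 2) {
    return(tibble::tibble(from = character(), to = character(),
                          count = integer()))
  }
  tibble::tibble(from = f[-length(f)], to = f[-1]) |>
    dplyr::count(.data$from, .data$to, name = "count")
}

#' Total and intraform transition summaries
#'
#' @param table A `transition_table` from [tabulate_transitions()].
#' @return Named list: `total` transitions, `intraform` count, and
#'   `intraform_share` (proportion of same-form moves).
#' @export
transition_summary <- function(table) {
  stopifnot(inherits(table, "transition_table"))
  total <- sum(table$count)
  intra <- sum(table$count[table$from == table$to])
  list(total = total, intraform = intra,
       intraform_share = if (total > 0) intra / total else NA_real_)
}

#' Gegear's floral constancy index
#'
#' CI = (c - e) / ((c + e) - 2ce), where c is a forager's observed
#' proportion of same-form transitions and e = p^2 + (1 - p)^2 the
#' proportion expected under random choice given p, its proportion of
#' visits to the focal form. Ranges from -1 (complete inconstancy)
#' through 0 (random foraging, c = e) to 1 (complete constancy). The
#' index is unchanged by swapping which form is focal (e is symmetric in
#' p and 1 - p). Undefined when c = e = 0 or c = e = 1; returned as NA.
#'
#' @param c Observed proportion of same-form transitions, in \[0, 1\].
#' @param p Proportion of visits to the focal form, in \[0, 1\].
#' @return CI in \[-1, 1\], or NA where undefined.
#' @export
#' @examples
#' gegear_ci(0.75, 0.6)  # 0.4694
gegear_ci <- function(c, p) {
  if (any(c < 0 | c > 1, na.rm = TRUE) || any(p < 0 | p > 1, na.rm = TRUE)) {
    ib_stop("c and p must be proportions in [0, 1]",
            "isobarrier_invalid_input")
  }
  e <- p^2 + (1 - p)^2
  denom <- (c + e) - 2 * c * e
  ifelse(denom == 0, NA_real_, (c - e) / denom)
}

#' Per-forager constancy records
#'
#' Computes c, p, e and Gegear's CI for every forager in a foraging log.
#' c and p are computed over the forager's whole observed bout set
#' (transitions within bouts only); p is the proportion of collapsed
#' plant-level visits to the focal form, which is the alphabetically
#' first label for determinism (the CI does not depend on this choice).
#' Foragers with no transitions, or with an undefined CI denominator, get
#' `ci = NA`.
#'
#' @inheritParams tabulate_transitions
#' @return Tibble: `forager_id`, `species`, `n_transitions`, `c`, `p`,
#'   `e`, `ci`.
#' @export
forager_constancy <- function(log, forms = c("white", "pink")) {
  table <- tabulate_transitions(log, forms)
  focal <- sort(forms)[1]
  per <- attr(table, "per_forager")
  if (!"bout_id" %in% names(log)) log$bout_id <- log$forager_id

  visits <- log |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$forager_id, .data$bout_id, .data$visit_index) |>
    dplyr::group_by(.data$forager_id, .data$species, .data$bout_id) |>
    dplyr::group_modify(function(d, key) {
      keep <- c(TRUE, d$plant_id[-1] != d$plant_id[-nrow(d)])
      tibble::tibble(n_visits = sum(keep),
                     n_focal = sum(d$form[keep] == focal))
    }) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$forager_id, .data$species) |>
    dplyr::summarise(p = sum(.data$n_focal) / sum(.data$n_visits),
                     .groups = "drop")

  trans <- per |>
    dplyr::group_by(.data$forager_id, .data$species) |>
    dplyr::summarise(
      n_transitions = sum(.data$count),
      c = sum(.data$count[.data$from == .data$to]) / sum(.data$count),
      .groups = "drop"
    )

  dplyr::left_join(visits, trans, by = c("forager_id", "species")) |>
    dplyr::mutate(
      n_transitions = ifelse(is.na(.data$n_transitions), 0L,
                             .data$n_transitions),
      e = .data$p^2 + (1 - .data$p)^2,
      ci = ifelse(is.na(.data$c), NA_real_, gegear_ci_safe(.data$c, .data$p))
    ) |>
    dplyr::select("forager_id", "species", "n_transitions",
                  "c", "p", "e", "ci")
}

# gegear_ci over vectors that may contain NA c values.
gegear_ci_safe <- function(c, p) {
  out <- rep(NA_real_, length(c))
  ok <- !is.na(c) & !is.na(p)
  out[ok] <- gegear_ci(c[ok], p[ok])
  out
}

#' Pollinator-isolation success pairs from a transition table
#'
#' For each maternal form, conspecific success is the count of same-form
#' transitions arriving at it and heterospecific success the count of
#' cross-form transitions arriving at it (pollen moves with the bee, so
#' arrivals at a form are potential pollinations of it).
#'
#' @param table A `transition_table` from [tabulate_transitions()].
#' @return Tibble with one row per maternal form: `barrier`,
#'   `maternal_form`, `conspecific`, `heterospecific`, `ri`.
#' @export
pollinator_success_pairs <- function(table) {
  stopifnot(inherits(table, "transition_table"))
  if (sum(table$count) == 0) {
    ib_stop("transition table is all zero: no foraging information",
            "isobarrier_undefined_ri")
  }
  forms <- attr(table, "forms")
  cnt <- function(from, to) table$count[table$from == from & table$to == to]
  out <- lapply(forms, function(f) {
    other <- setdiff(forms, f)
    tibble::tibble(barrier = "pollinator", maternal_form = f,
                   conspecific = cnt(f, f), heterospecific = cnt(other, f))
  })
  out <- dplyr::bind_rows(out)
  dplyr::mutate(out, ri = pairwise_ri(.data$conspecific,
                                      .data$heterospecific))
}

#' Species-level constancy summary
#'
#' Mean and standard deviation of Gegear's CI per pollinator species,
#' excluding foragers with undefined CI (their count is reported).
#'
#' @param records Output of [forager_constancy()].
#' @return Tibble: `species`, `n` (defined CIs), `n_undefined`, `mean_ci`,
#'   `sd_ci` (0 when n = 1).
#' @export
species_ci_summary <- function(records) {
  records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = sum(!is.na(.data$ci)),
      n_undefined = sum(is.na(.data$ci)),
      mean_ci = mean(.data$ci, na.rm = TRUE),
      sd_ci = ifelse(sum(!is.na(.data$ci)) > 1,
                     stats::sd(.data$ci, na.rm = TRUE), 0),
      .groups = "drop"
    )
}
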