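# File formats: all tables are plain UTF-8 CSV/TSV with a header row;
# dates are ISO-8601; serialized numbers keep full precision (rounding
# happens only at report rendering).

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) {
    ib_stop(sprintf("%s file not found: %s", what, path),
            "isobarrier_io_error")
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) {
      ib_stop(sprintf("could not parse %s file %s: %s", what, path,
                      conditionMessage(e)), "isobarrier_io_error")
    })
  if (nrow(df) == 0) {
    ib_stop(sprintf("%s file is empty: %s", what, path),
            "isobarrier_io_error")
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ib_stop(sprintf("%s file %s lacks column(s): %s", what, path,
                    paste(missing, collapse = ", ")),
            "isobarrier_io_error")
  }
  for (col in required) {
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad) > 0) {
      ib_stop(sprintf("%s file %s: missing '%s' at data row(s) %s", what,
                      path, col,
                      paste(utils::head(bad, 5), collapse = ", ")),
              "isobarrier_io_error")
    }
  }
  tibble::as_tibble(df)
}

#' Read flowering intervals from CSV
#'
#' Expected columns: `form`, `first_day`, `last_day` (ISO-8601 dates).
#' Extra columns are kept as metadata in the `extra` attribute.
#'
#' @param path CSV path.
#' @return Named list of [flowering_interval()]s.
#' @export
read_flowering <- function(path) {
  df <- read_checked_csv(path, c("form", "first_day", "last_day"),
                         "flowering-interval")
  out <- lapply(seq_len(nrow(df)), function(i) {
    flowering_interval(df$form[i], df$first_day[i], df$last_day[i])
  })
  names(out) <- df$form
  attr(out, "extra") <- df[setdiff(names(df),
                                   c("form", "first_day", "last_day"))]
  out
}

#' Write flowering intervals to CSV
#'
#' @param intervals Named list of [flowering_interval()]s.
#' @param path Output CSV path.
#' @export
write_flowering <- function(intervals, path) {
  df <- dplyr::bind_rows(lapply(intervals, function(x) {
    tibble::tibble(form = x$form,
                   first_day = format(x$first_day),
                   last_day = format(x$last_day))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a pollinator foraging log from CSV
#'
#' Expected columns: `forager_id`, `species`, `visit_index`, `plant_id`,
#' `form`; optional `bout_id`.
#'
#' @param path CSV path.
#' @return Foraging log tibble.
#' @export
read_foraging_log <- function(path) {
  read_checked_csv(path, c("forager_id", "species", "visit_index",
                           "plant_id", "form"), "foraging-log")
}

#' Read crossing-trial outcomes from CSV
#'
#' Expected columns: `maternal_form`, `treatment`, `fruit` (0/1),
#' `pollen_tubes`; optional seed-category counts `seeds_large`,
#' `seeds_small`, `seeds_aborted`, `seeds_empty`.
#'
#' @param path CSV path.
#' @return Crossing-trial tibble.
#' @export
read_crossing_trials <- function(path) {
  read_checked_csv(path, c("maternal_form", "treatment", "fruit",
                           "pollen_tubes"), "crossing-trial")
}

#' Read pre-summarised barrier success pairs from CSV
#'
#' For studies where only summary statistics are available (e.g. printed
#' means rather than raw trials). Expected columns: `barrier`,
#' `maternal_form`, `conspecific`, `heterospecific`; optional `n`.
#'
#' @param path CSV path.
#' @return Tibble of success pairs.
#' @export
read_barrier_summaries <- function(path) {
  df <- read_checked_csv(path, c("barrier", "maternal_form", "conspecific",
                                 "heterospecific"), "barrier-summary")
  if (!"n" %in% names(df)) df$n <- NA_integer_
  df
}

#' Read spectra from a wide CSV
#'
#' First column `wavelength_nm` (or `wavelength`), one spectrum per
#' subsequent column.
#'
#' @param path CSV path.
#' @param kind Spectrum kind for all columns (default reflectance).
#' @return Named list of [spectrum()]s.
#' @export
read_spectra <- function(path, kind = "reflectance") {
  df <- read_checked_csv(path, character(0), "spectra")
  wl_col <- intersect(c("wavelength_nm", "wavelength"), names(df))[1]
  if (is.na(wl_col)) {
    ib_stop(sprintf("spectra file %s lacks a wavelength_nm column", path),
            "isobarrier_io_error")
  }
  others <- setdiff(names(df), wl_col)
  if (length(others) == 0) {
    ib_stop(sprintf("spectra file %s contains no spectrum columns", path),
            "isobarrier_io_error")
  }
  out <- lapply(others, function(nm) spectrum(df[[wl_col]], df[[nm]], kind))
  stats::setNames(out, others)
}

#' Write spectra to a wide CSV
#'
#' @param spectra Named list of [spectrum()]s on a common grid.
#' @param path Output CSV path.
#' @export
write_spectra <- function(spectra, path) {
  wl <- spectra[[1]]$wavelength
  for (s in spectra) {
    if (!identical(s$wavelength, wl)) {
      ib_stop("all spectra must share one wavelength grid to be written",
              "isobarrier_invalid_input")
    }
  }
  df <- data.frame(wavelength_nm = wl)
  for (nm in names(spectra)) df[[nm]] <- spectra[[nm]]$value
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build a transition table from pre-tabulated counts
#'
#' For studies where only aggregated transition counts are available.
#'
#' @param counts Data frame with columns `from`, `to`, `count`.
#' @param forms The two form labels.
#' @return A `transition_table` compatible with
#'   [pollinator_success_pairs()].
#' @export
transition_table_from_counts <- function(counts, forms = c("white", "pink")) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("from", "to", "count") %in% names(counts))) {
    ib_stop("counts must have columns from, to, count",
            "isobarrier_invalid_input")
  }
  bad <- setdiff(unique(c(counts$from, counts$to)), forms)
  if (length(bad) > 0) {
    ib_stop(sprintf("unknown form label(s): %s", paste(bad, collapse = ", ")),
            "isobarrier_invalid_input")
  }
  grid <- tidyr_expand_forms(forms)
  out <- dplyr::left_join(grid, counts, by = c("from", "to")) |>
    dplyr::mutate(count = ifelse(is.na(.data$count), 0L,
                                 as.integer(.data$count)))
  structure(out, per_forager = NULL, forms = forms,
            class = c("transition_table", class(out)))
}

#' Summarise crossing trials into per-barrier success pairs
#'
#' Extracts the three postpollination barriers from raw crossing trials,
#' per maternal form: pollinia-pistil interaction (mean pollen tubes
#' entering the ovary, intraform vs interform), fruit production (mean
#' fruit set), and seed development (mean large-embryo rate among
#' fruiting flowers).
#'
#' @param trials Tibble from [read_crossing_trials()] or
#'   [simulate_crossings()].
#' @return Tibble: `barrier`, `maternal_form`, `conspecific`,
#'   `heterospecific`, `n` (trials behind the conspecific mean).
#' @export
crossing_success_pairs <- function(trials) {
  forms <- unique(trials$maternal_form)
  have_seeds <- all(c("seeds_large", "seeds_small", "seeds_aborted",
                      "seeds_empty") %in% names(trials))
  rows <- lapply(forms, function(f) {
    intra <- trials[trials$maternal_form == f &
                      trials$treatment == "intraform", ]
    inter <- trials[trials$maternal_form == f &
                      trials$treatment == "interform", ]
    if (nrow(intra) == 0 || nrow(inter) == 0) {
      ib_stop(sprintf(
        "maternal form %s lacks intraform and/or interform trials", f),
        "isobarrier_invalid_input")
    }
    out <- tibble::tibble(
      barrier = c("pollen_tube", "fruit"),
      maternal_form = f,
      conspecific = c(mean(intra$pollen_tubes), mean(intra$fruit)),
      heterospecific = c(mean(inter$pollen_tubes), mean(inter$fruit)),
      n = nrow(intra)
    )
    if (have_seeds) {
      rate <- function(d) {
        d <- d[!is.na(d$seeds_large), ]
        if (nrow(d) == 0) return(NA_real_)
        tot <- d$seeds_large + d$seeds_small + d$seeds_aborted +
          d$seeds_empty
        mean(d$seeds_large / tot)
      }
      out <- dplyr::bind_rows(out, tibble::tibble(
        barrier = "seed", maternal_form = f,
        conspecific = rate(intra), heterospecific = rate(inter),
        n = sum(!is.na(intra$seeds_large))
      ))
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Read a study configuration from YAML
#'
#' Relative paths in the file are resolved against its directory.
#'
#' @param path YAML path.
#' @return Configuration list for [run_pipeline()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) {
    ib_stop(sprintf("config file not found: %s", path),
            "isobarrier_io_error")
  }
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("flowering", "foraging", "transitions", "crossings",
                "barriers", "spectra")) {
    if (!is.null(cfg[[key]]) && !grepl("^/", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  cfg
}
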