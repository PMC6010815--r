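#' Run the full reproductive-isolation pipeline
#'
#' Reads the study inputs, computes every barrier's RI in both maternal
#' directions with asymmetries, composes the sequential cascade into
#' total RI with per-barrier contributions, summarises pollinator
#' constancy, and places any reflectance spectra in the colour hexagon.
#' Writes the barrier, cascade, constancy and vision tables as TSV plus a
#' JSON summary into `out_dir`, and returns everything invisibly.
#'
#' Configuration (list or path to a YAML file; relative paths resolve
#' against the YAML's directory):
#' \describe{
#'   \item{flowering}{CSV of flowering intervals (required).}
#'   \item{foraging}{CSV foraging log, or \code{transitions}: CSV of
#'     pre-tabulated from/to/count transition counts. One of the two is
#'     required for the pollinator barrier.}
#'   \item{crossings}{CSV of raw crossing trials, or \code{barriers}: CSV
#'     of pre-summarised success pairs. One of the two is required.}
#'   \item{spectra}{optional wide CSV of reflectance spectra.}
#'   \item{forms}{the two form labels (default white, pink).}
#'   \item{barrier_order}{post-phenology barrier order (default
#'     pollinator, pollen_tube, fruit, seed).}
#'   \item{vision}{list: \code{species} (honeybee/bumblebee) and
#'     \code{jnd} threshold (default 0.1).}
#'   \item{bootstrap}{list: \code{B} resamples and \code{seed}; intervals
#'     are computed only where raw per-trial data exist.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config Configuration list or YAML path.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list: `barrier_table`, `cascade`, `constancy`,
#'   `vision`, `summary` (the JSON content), `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_study_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    ib_stop("no output directory given", "isobarrier_config_error")
  forms <- config$forms %||% c("white", "pink")
  order <- config$barrier_order %||%
    c("pollinator", "pollen_tube", "fruit", "seed")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      ib_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)), "isobarrier_pipeline_error")
    })
  }

  # -- phenology ------------------------------------------------------
  if (is.null(config$flowering)) {
    ib_stop("config lacks a flowering-interval file",
            "isobarrier_config_error")
  }
  phen <- stage("phenology", {
    ints <- read_flowering(config$flowering)
    if (!all(forms %in% names(ints))) {
      ib_stop(sprintf("flowering file lacks form(s): %s",
                      paste(setdiff(forms, names(ints)), collapse = ", ")),
              "isobarrier_config_error")
    }
    lapply(stats::setNames(forms, forms), function(f) {
      other <- setdiff(forms, f)
      ov <- overlap_days(ints[[f]], ints[[other]])
      list(shared = ov$shared, unshared = ov$unshared,
           ri = phenology_ri(ov$shared, ov$unshared))
    })
  })

  # -- pollinator barrier + constancy ---------------------------------
  constancy_out <- NULL
  trans_table <- stage("pollinator", {
    if (!is.null(config$foraging)) {
      log <- read_foraging_log(config$foraging)
      constancy_out <- forager_constancy(log, forms)
      tabulate_transitions(log, forms)
    } else if (!is.null(config$transitions)) {
      transition_table_from_counts(
        utils::read.csv(config$transitions, stringsAsFactors = FALSE),
        forms)
    } else {
      ib_stop("config needs either a foraging log or transition counts",
              "isobarrier_config_error")
    }
  })
  poll_pairs <- pollinator_success_pairs(trans_table)

  # -- postpollination barriers ---------------------------------------
  boot_obs <- NULL
  post_pairs <- stage("crossings", {
    if (!is.null(config$crossings)) {
      boot_obs <- read_crossing_trials(config$crossings)
      crossing_success_pairs(boot_obs)
    } else if (!is.null(config$barriers)) {
      read_barrier_summaries(config$barriers)
    } else {
      ib_stop("config needs either raw crossings or barrier summaries",
              "isobarrier_config_error")
    }
  })

  # -- barrier table with asymmetries ---------------------------------
  pairs <- dplyr::bind_rows(
    tibble::tibble(barrier = "phenology", maternal_form = forms,
                   conspecific = vapply(forms, function(f)
                     as.numeric(phen[[f]]$shared), numeric(1)),
                   heterospecific = vapply(forms, function(f)
                     as.numeric(phen[[f]]$unshared), numeric(1)),
                   n = NA_integer_),
    dplyr::select(poll_pairs, -"ri") |>
      dplyr::mutate(n = NA_integer_),
    dplyr::select(post_pairs, "barrier", "maternal_form", "conspecific",
                  "heterospecific", "n")
  )
  pairs$ri <- ifelse(
    pairs$barrier == "phenology",
    1 - pairs$conspecific / (pairs$conspecific + pairs$heterospecific),
    pairwise_ri(pairs$conspecific, pairs$heterospecific))
  pairs <- add_bootstrap_intervals(pairs, boot_obs, config$bootstrap)
  asym <- pairs |>
    dplyr::group_by(.data$barrier) |>
    dplyr::summarise(asymmetry = if (dplyr::n() == 2)
      abs(diff(.data$ri)) else NA_real_, .groups = "drop")
  barrier_table <- dplyr::left_join(pairs, asym, by = "barrier")

  # -- cascade --------------------------------------------------------
  cascades <- stage("cascade", {
    lapply(stats::setNames(forms, forms), function(f) {
      b <- barrier_table[barrier_table$maternal_form == f &
                           barrier_table$barrier %in% order, ]
      missing <- setdiff(order, b$barrier)
      if (length(missing) > 0) {
        ib_stop(sprintf("barrier order references missing barrier(s): %s",
                        paste(missing, collapse = ", ")),
                "isobarrier_config_error")
      }
      b <- b[match(order, b$barrier), ]
      barrier_cascade(f, phen[[f]]$shared, phen[[f]]$unshared, b)
    })
  })
  comparison <- compare_directions(cascades[[1]], cascades[[2]])
  cascade_table <- dplyr::bind_rows(lapply(forms, function(f) {
    dplyr::mutate(tibble::as_tibble(comparison$results[[f]]),
                  maternal_form = f, .before = 1)
  }))

  # -- vision ---------------------------------------------------------
  vision_out <- NULL
  if (!is.null(config$spectra)) {
    vision_out <- stage("vision", {
      spectra <- read_spectra(config$spectra)
      vm <- vision_model(config$vision$species %||% "honeybee")
      loci <- hexagon_loci(lapply(spectra, resample_spectrum), vm)
      dm <- chromatic_distance_matrix(loci,
                                      config$vision$jnd %||% 0.1)
      list(model = vm$meta, loci = loci, distances = dm)
    })
  }

  # -- outputs --------------------------------------------------------
  paths <- list(
    barriers = file.path(out_dir, "barrier_table.tsv"),
    cascade = file.path(out_dir, "cascade_table.tsv"),
    summary = file.path(out_dir, "summary.json")
  )
  write_tsv_plain(barrier_table, paths$barriers)
  write_tsv_plain(cascade_table, paths$cascade)
  if (!is.null(constancy_out)) {
    paths$constancy <- file.path(out_dir, "constancy_table.tsv")
    write_tsv_plain(constancy_out, paths$constancy)
    paths$constancy_species <- file.path(out_dir, "constancy_species.tsv")
    write_tsv_plain(species_ci_summary(constancy_out),
                    paths$constancy_species)
  }
  if (!is.null(vision_out)) {
    paths$vision_loci <- file.path(out_dir, "vision_loci.tsv")
    write_tsv_plain(vision_out$loci, paths$vision_loci)
    paths$vision_pairs <- file.path(out_dir, "vision_distances.tsv")
    write_tsv_plain(vision_out$distances$pairs, paths$vision_pairs)
  }

  summary <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("isobarrier")),
    barrier_order = order,
    phenology = lapply(phen, function(x)
      list(shared_days = x$shared, unshared_days = x$unshared,
           ri = x$ri, ri_2dp = round_half_up(x$ri))),
    total_ri = as.list(comparison$totals),
    total_ri_2dp = as.list(round_half_up(comparison$totals)),
    per_stage_asymmetry = stats::setNames(
      as.list(comparison$asymmetry$asymmetry),
      comparison$asymmetry$barrier),
    vision = if (!is.null(vision_out)) vision_out$model else NULL,
    seed = config$bootstrap$seed %||% NULL
  )
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null")

  invisible(list(barrier_table = barrier_table,
                 cascade = comparison,
                 cascade_table = cascade_table,
                 constancy = constancy_out,
                 vision = vision_out,
                 summary = summary,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Attach percentile bootstrap intervals where raw trial data exist.
add_bootstrap_intervals <- function(pairs, trials, boot_cfg) {
  pairs$ci_low <- NA_real_
  pairs$ci_high <- NA_real_
  if (is.null(trials) || is.null(boot_cfg)) return(pairs)
  B <- boot_cfg$B %||% 2000
  seed <- boot_cfg$seed %||% 1
  obs_for <- function(barrier, form, treatment) {
    d <- trials[trials$maternal_form == form &
                  trials$treatment == treatment, ]
    switch(barrier,
           pollen_tube = d$pollen_tubes,
           fruit = d$fruit,
           seed = {
             d <- d[!is.na(d$seeds_large), ]
             tot <- d$seeds_large + d$seeds_small + d$seeds_aborted +
               d$seeds_empty
             d$seeds_large / tot
           },
           NULL)
  }
  for (i in seq_len(nrow(pairs))) {
    con <- obs_for(pairs$barrier[i], pairs$maternal_form[i], "intraform")
    het <- obs_for(pairs$barrier[i], pairs$maternal_form[i], "interform")
    if (is.null(con) || length(con) < 2 || length(het) < 2) next
    ci <- ri_bootstrap_ci(con, het, B = B, seed = seed)
    pairs$ci_low[i] <- ci$low
    pairs$ci_high[i] <- ci$high
  }
  pairs
}
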