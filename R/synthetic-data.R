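#' Simulation configuration
#'
#' Default parameters describe a two-form study of the kind the package
#' analyses: two colour forms with broadly overlapping ~7-week flowering
#' windows, a high-constancy and a lower-constancy bee species foraging
#' over an equal 20:20 availability array, a four-treatment crossing
#' design (self, intraform, interform, unmanipulated control) with
#' treatment-dependent fruit probabilities, overdispersed pollen-tube
#' counts, four-category embryo composition scored on ~300 seeds per
#' fruit, and white / pink / intermediate reflectance spectra.
#'
#' @param ... Named overrides of the defaults; nested lists are merged
#'   recursively (e.g. `foraging = list(availability = c(white = 30,
#'   pink = 10))`).
#' @param seed Integer seed; every generator derives its stream from it.
#' @return A `simulation_config` (nested named list).
#' @export
simulation_config <- function(..., seed = 1L) {
  base <- list(
    seed = as.integer(seed),
    forms = c("white", "pink"),
    phenology = list(
      n_plants = c(white = 77, pink = 40),
      window = list(white = c("2016-07-24", "2016-08-31"),
                    pink = c("2016-07-31", "2016-09-05")),
      flower_lifespan_mean = 10, flower_lifespan_sd = 2
    ),
    foraging = list(
      availability = c(white = 20, pink = 20),
      species = list(
        list(species = "apis_like", kappa = 0.95, n_foragers = 30,
             bout_mean = 10),
        list(species = "bombus_like", kappa = 0.85, n_foragers = 26,
             bout_mean = 10)
      )
    ),
    crossing = list(
      n_per_cell = 30,
      seeds_per_fruit = 300,
      tube_dispersion = 1.5,
      tube_mean = list(
        white = c(self = 146.3, intraform = 118.93, interform = 125.62),
        pink = c(self = 42.33, intraform = 83.95, interform = 69.75)
      ),
      fruit_p = list(
        white = c(self = 0.8, intraform = 0.8, interform = 0.35,
                  control = 0),
        pink = c(self = 0.76, intraform = 0.76, interform = 0.67,
                 control = 0)
      ),
      embryo_p = list(
        white = list(
          self = c(large = 0.7194, small = 0.11, aborted = 0.09,
                   empty = 0.0806),
          intraform = c(large = 0.7242, small = 0.11, aborted = 0.09,
                        empty = 0.0758),
          interform = c(large = 0.4551, small = 0.22, aborted = 0.16,
                        empty = 0.1649)
        ),
        pink = list(
          self = c(large = 0.5085, small = 0.20, aborted = 0.15,
                   empty = 0.1415),
          intraform = c(large = 0.6548, small = 0.14, aborted = 0.10,
                        empty = 0.1052),
          interform = c(large = 0.6335, small = 0.15, aborted = 0.11,
                        empty = 0.1065)
        )
      )
    ),
    spectra = list(
      n = c(white = 35, pink = 31, intermediate = 10),
      noise_sd = 0.005,
      intermediate_weight = 0.75
    )
  )
  cfg <- modify_list_deep(base, list(...))
  validate_simulation_config(cfg)
  structure(cfg, class = c("simulation_config", "list"))
}

# Recursive modifyList that merges nested lists.
modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_simulation_config <- function(cfg) {
  for (sp in cfg$foraging$species) {
    if (sp$kappa < 0 || sp$kappa > 1) {
      ib_stop(sprintf("kappa for %s must lie in [0, 1]", sp$species),
              "isobarrier_invalid_input")
    }
  }
  if (any(cfg$phenology$n_plants <= 0) ||
      any(cfg$foraging$availability <= 0)) {
    ib_stop("plant counts and availabilities must be positive",
            "isobarrier_invalid_input")
  }
  for (form in names(cfg$crossing$embryo_p)) {
    for (tr in names(cfg$crossing$embryo_p[[form]])) {
      p <- cfg$crossing$embryo_p[[form]][[tr]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        ib_stop(sprintf("embryo probabilities for %s/%s are not a simplex",
                        form, tr),
                "isobarrier_invalid_input")
      }
    }
  }
  for (form in names(cfg$crossing$fruit_p)) {
    p <- cfg$crossing$fruit_p[[form]]
    if (any(p < 0 | p > 1)) {
      ib_stop("fruit probabilities must lie in [0, 1]",
              "isobarrier_invalid_input")
    }
  }
  invisible(cfg)
}

#' Simulate flowering phenology
#'
#' Each plant's first-flower date is uniform within its form's window;
#' its scape then flowers for a span drawn around the mean flower
#' lifespan. The form-level interval is the union of its plants'
#' intervals.
#'
#' @param config A [simulation_config()].
#' @return Named list: `intervals` (one [flowering_interval()] per form)
#'   and `plants` tibble (`form`, `plant_id`, `first_day`, `last_day`).
#' @export
simulate_phenology <- function(config) {
  set.seed(config$seed + 101L)
  ph <- config$phenology
  plants <- lapply(config$forms, function(form) {
    w <- ib_as_date(ph$window[[form]], sprintf("window for %s", form))
    if (w[2] < w[1]) {
      ib_stop(sprintf("empty flowering window for %s", form),
              "isobarrier_invalid_input")
    }
    n <- ph$n_plants[[form]]
    start <- w[1] + sample.int(as.integer(w[2] - w[1]) + 1L, n,
                               replace = TRUE) - 1L
    span <- pmax(1, round(stats::rnorm(n, ph$flower_lifespan_mean,
                                       ph$flower_lifespan_sd)))
    tibble::tibble(form = form,
                   plant_id = sprintf("%s_%03d", form, seq_len(n)),
                   first_day = start, last_day = start + span - 1)
  })
  plants <- dplyr::bind_rows(plants)
  intervals <- lapply(config$forms, function(form) {
    d <- plants[plants$form == form, ]
    flowering_interval(form, min(d$first_day), max(d$last_day))
  })
  names(intervals) <- config$forms
  list(intervals = intervals, plants = plants)
}

#' Simulate pollinator foraging bouts
#'
#' Each forager is a two-state Markov chain over the colour forms: with
#' probability kappa it stays on the form it is currently visiting,
#' otherwise it chooses a form in proportion to availability. The first
#' visit of a bout is availability-weighted. Successive visits are always
#' to a different plant of the chosen form, so every move is a
#' plant-level transition. At kappa = 0 the chain is availability-random
#' (expected constancy index 0 under equal availability); at kappa = 1
#' every forager is completely constant.
#'
#' @param config A [simulation_config()].
#' @return Foraging log tibble: `forager_id`, `species`, `bout_id`,
#'   `visit_index`, `plant_id`, `form`.
#' @export
simulate_foraging <- function(config) {
  set.seed(config$seed + 202L)
  avail <- config$foraging$availability
  forms <- names(avail)
  pav <- avail / sum(avail)
  bouts <- list()
  for (sp in config$foraging$species) {
    for (i in seq_len(sp$n_foragers)) {
      len <- 2L + stats::rgeom(1, 1 / max(1, sp$bout_mean - 1))
      form_seq <- character(len)
      form_seq[1] <- sample(forms, 1, prob = pav)
      for (v in seq_len(len - 1L)) {
        form_seq[v + 1L] <-
          if (stats::runif(1) < sp$kappa) form_seq[v]
          else sample(forms, 1, prob = pav)
      }
      pick_seq <- integer(len)
      for (v in seq_len(len)) {
        k <- avail[[form_seq[v]]]
        prev <- if (v > 1L && form_seq[v - 1L] == form_seq[v]) {
          pick_seq[v - 1L]
        } else 0L
        candidates <- setdiff(seq_len(k), prev)
        pick_seq[v] <- candidates[sample.int(length(candidates), 1)]
      }
      plant_seq <- sprintf("%s_%02d", form_seq, pick_seq)
      bouts[[length(bouts) + 1L]] <- tibble::tibble(
        forager_id = sprintf("%s_%02d", sp$species, i),
        species = sp$species,
        bout_id = sprintf("%s_%02d_b1", sp$species, i),
        visit_index = seq_len(len),
        plant_id = plant_seq,
        form = form_seq
      )
    }
  }
  dplyr::bind_rows(bouts)
}

#' Simulate the crossing experiment
#'
#' One row per hand-pollinated (or control) flower: fruit set is
#' Bernoulli with the cell's probability, pollen-tube counts are negative
#' binomial (mean and dispersion per cell; the field counts are strongly
#' overdispersed, with standard deviations close to the means), and each
#' fruit's seed lot is a multinomial draw of ~300 seeds over the four
#' embryo categories (large, small, aborted, empty). Control cells with
#' probability 0 never set fruit. Seed categories are only scored on
#' flowers that set fruit.
#'
#' @param config A [simulation_config()].
#' @return Tibble: `maternal_form`, `treatment`, `flower_id`, `fruit`,
#'   `pollen_tubes`, `seeds_large`, `seeds_small`, `seeds_aborted`,
#'   `seeds_empty` (seed columns NA when no fruit).
#' @export
simulate_crossings <- function(config) {
  set.seed(config$seed + 303L)
  cr <- config$crossing
  out <- list()
  for (form in config$forms) {
    for (tr in names(cr$fruit_p[[form]])) {
      n <- cr$n_per_cell
      fruit <- stats::rbinom(n, 1, cr$fruit_p[[form]][[tr]])
      tubes <- if (tr %in% names(cr$tube_mean[[form]])) {
        stats::rnbinom(n, size = cr$tube_dispersion,
                       mu = cr$tube_mean[[form]][[tr]])
      } else {
        rep(0L, n)  # controls: no pollinarium placed
      }
      seeds <- matrix(NA_integer_, n, 4)
      if (tr %in% names(cr$embryo_p[[form]])) {
        p <- cr$embryo_p[[form]][[tr]]
        idx <- which(fruit == 1)
        if (length(idx) > 0) {
          seeds[idx, ] <- t(stats::rmultinom(length(idx),
                                             cr$seeds_per_fruit, p))
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        maternal_form = form, treatment = tr,
        flower_id = sprintf("%s_%s_%02d", form, tr, seq_len(n)),
        fruit = fruit, pollen_tubes = tubes,
        seeds_large = seeds[, 1], seeds_small = seeds[, 2],
        seeds_aborted = seeds[, 3], seeds_empty = seeds[, 4]
      )
    }
  }
  dplyr::bind_rows(out)
}

# Parametric mean reflectance curves for the three colour types.
spectral_profile <- function(type, grid = canonical_grid()) {
  white <- 0.05 + 0.75 / (1 + exp(-(grid - 400) / 15))
  pink <- 0.05 + 0.6 / (1 + exp(-(grid - 590) / 15)) +
    0.15 * exp(-((grid - 430) / 40)^2)
  switch(type,
         white = white,
         pink = pink,
         intermediate = NA)  # handled by caller via mixture weight
}

#' Simulate floral reflectance spectra
#'
#' Smooth parametric curves plus Gaussian noise, clipped to \[0, 1\]:
#' white-like spectra are high and flat across the human-visible range,
#' pink-like spectra reflect strongly at long wavelengths with a
#' secondary blue bump and little in the green band, and intermediates
#' are a mixture weighted toward white (the dusky-blush phenotype is
#' nearly indistinguishable from white to a bee).
#'
#' @param config A [simulation_config()].
#' @return Named list of reflectance [spectrum()]s (`white_1`, ...,
#'   `pink_1`, ..., `intermediate_1`, ...).
#' @export
simulate_spectra <- function(config) {
  set.seed(config$seed + 404L)
  sp <- config$spectra
  grid <- canonical_grid()
  w <- spectral_profile("white", grid)
  p <- spectral_profile("pink", grid)
  means <- list(white = w, pink = p,
                intermediate = sp$intermediate_weight * w +
                  (1 - sp$intermediate_weight) * p)
  out <- list()
  for (type in names(sp$n)) {
    for (i in seq_len(sp$n[[type]])) {
      v <- means[[type]] + stats::rnorm(length(grid), 0, sp$noise_sd)
      v <- pmin(1, pmax(0, v))
      out[[sprintf("%s_%d", type, i)]] <- spectrum(grid, v, "reflectance")
    }
  }
  out
}

#' Generate a complete synthetic study on disk
#'
#' Writes every input file the pipeline reads — flowering intervals,
#' foraging log, crossing trials, spectra — plus a provenance JSON
#' recording the seed and a hash of the configuration.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
simulate_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- simulate_phenology(config)
  flog <- simulate_foraging(config)
  cross <- simulate_crossings(config)
  spectra <- simulate_spectra(config)

  paths <- list(
    flowering = file.path(dir, "flowering.csv"),
    foraging = file.path(dir, "foraging_log.csv"),
    crossings = file.path(dir, "crossing_trials.csv"),
    spectra = file.path(dir, "spectra.csv"),
    provenance = file.path(dir, "provenance.json")
  )
  write_flowering(ph$intervals, paths$flowering)
  utils::write.csv(flog, paths$foraging, row.names = FALSE)
  utils::write.csv(cross, paths$crossings, row.names = FALSE)
  write_spectra(spectra, paths$spectra)
  jsonlite::write_json(
    list(seed = config$seed,
         config_hash = config_hash(config),
         generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paths$provenance, auto_unbox = TRUE)
  invisible(paths)
}

#' Read a simulation configuration from YAML
#'
#' Values in the file override the [simulation_config()] defaults; the
#' shipped `extdata/config/paper_like.yaml` writes the defaults out in
#' full.
#'
#' @param path YAML path.
#' @param seed Seed used when the file does not set one.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path, seed = 1L) {
  if (!file.exists(path)) {
    ib_stop(sprintf("simulation config not found: %s", path),
            "isobarrier_io_error")
  }
  y <- yaml_leaves_to_vectors(yaml::read_yaml(path))
  seed <- y$seed %||% seed
  y$seed <- NULL
  do.call(simulation_config, c(y, list(seed = seed)))
}

# YAML maps arrive as lists; collapse leaf-level lists of same-typed
# scalars into the vectors the generators expect (mixed-type records,
# like a forager species entry, stay lists).
yaml_leaves_to_vectors <- function(x) {
  if (!is.list(x)) return(x)
  scalar <- vapply(x, function(e) !is.list(e) && length(e) == 1, logical(1))
  type_of <- function(e) if (is.numeric(e)) "numeric" else class(e)[1]
  same_type <- length(unique(vapply(x, type_of, character(1)))) == 1
  if (length(x) > 0 && all(scalar) && same_type) {
    return(unlist(x))
  }
  lapply(x, yaml_leaves_to_vectors)
}

# Stable content hash of a configuration (small polynomial rolling
# hash; avoids a digest dependency).
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
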