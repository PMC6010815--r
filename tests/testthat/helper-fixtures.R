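# Shared fixture builders for the test suite.

# A foraging log from a compact string like "W W P P" (one forager, one
# bout, distinct plants unless an explicit plant vector is given).
make_log <- function(forms, plants = NULL, forager = "f1",
                     species = "apis_like") {
  forms_full <- ifelse(forms == "W", "white", "pink")
  if (is.null(plants)) plants <- sprintf("plant_%d", seq_along(forms))
  tibble::tibble(
    forager_id = forager, species = species,
    visit_index = seq_along(forms_full),
    plant_id = plants, form = forms_full
  )
}

# The published-summary fixture shipped with the package.
paper_fixture_config <- function() {
  system.file("extdata", "paper_fixture", "config.yaml",
              package = "isobarrier")
}

# Cascade built from the published white-direction inputs.
white_paper_cascade <- function() {
  barrier_cascade("white", shared = 41, unshared = 7, data.frame(
    barrier = c("pollinator", "pollen_tube", "fruit", "seed"),
    conspecific = c(370, 118.93, 1, 72.42),
    heterospecific = c(20, 125.62, h_from_ri(0.39), 45.51)
  ))
}

# Expected pollinator relative success of the two-state Markov forager:
# stationary visit shares equal availability, so arrivals at form f come
# from f with rate a_f * (kappa + (1 - kappa) a_f) and from the other
# form with rate a_o * (1 - kappa) a_f.
markov_pollinator_h <- function(kappa, availability, maternal) {
  a <- availability / sum(availability)
  af <- a[[maternal]]
  ao <- 1 - af
  (ao * (1 - kappa) * af) / (af * (kappa + (1 - kappa) * af))
}
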