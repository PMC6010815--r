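test_that("tabulate_transitions counts moves and reproduces the published table", {
  log <- make_log(c("W", "W", "W"))
  tt <- tabulate_transitions(log)
  expect_equal(tt$count[tt$from == "white" & tt$to == "white"], 2L)
  expect_equal(sum(tt$count), 2L)

  tt2 <- tabulate_transitions(make_log(c("W", "P")))
  expect_equal(tt2$count[tt2$from == "white" & tt2$to == "pink"], 1L)

  # the published counts, rebuilt as a counts table
  paper <- transition_table_from_counts(data.frame(
    from = c("white", "white", "pink", "pink"),
    to = c("white", "pink", "pink", "white"),
    count = c(370, 20, 64, 20)))
  s <- transition_summary(paper)
  expect_equal(s$total, 474L)
  expect_equal(s$intraform, 434L)
  expect_equal(round(100 * s$intraform_share, 2), 91.56)
})

test_that("repeat visits to one plant are collapsed; bouts never bridge", {
  log <- make_log(c("W", "W", "P"), plants = c("p1", "p1", "p2"))
  tt <- tabulate_transitions(log)
  expect_equal(sum(tt$count), 1L)  # only p1 -> p2
  expect_equal(tt$count[tt$from == "white" & tt$to == "pink"], 1L)

  two_bouts <- rbind(
    cbind(make_log(c("W", "W")), bout_id = "b1"),
    cbind(make_log(c("P", "P")), bout_id = "b2"))
  tt2 <- tabulate_transitions(two_bouts)
  # no white->pink bridge between the bouts
  expect_equal(tt2$count[tt2$from == "white" & tt2$to == "pink"], 0L)
  expect_equal(sum(tt2$count), 2L)
})

test_that("unknown labels error; single-visit bouts yield no transitions", {
  expect_error(tabulate_transitions(make_log("W", plants = "p1")[0, ]),
               NA)  # empty log tabulates to all-zero counts
  bad <- make_log(c("W", "P")); bad$form[2] <- "blue"
  expect_error(tabulate_transitions(bad),
               class = "isobarrier_invalid_input")
  single <- make_log("W")
  expect_equal(sum(tabulate_transitions(single)$count), 0L)
})

test_that("gegear_ci matches hand-computed values and boundaries", {
  # one bout W,W,W,P,P: c = 3/4, p = 3/5, e = 0.52, CI = 0.23/0.49
  expect_equal(gegear_ci(0.75, 0.6), 0.23 / 0.49)
  rec <- forager_constancy(make_log(c("W", "W", "W", "P", "P")))
  expect_equal(rec$c, 0.75)
  # focal form is the alphabetically first label ("pink"), so p = 2/5;
  # e and the CI are invariant to the choice
  expect_equal(rec$p, 0.4)
  expect_equal(rec$e, 0.52)
  expect_equal(rec$ci, 0.23 / 0.49)

  # boundary grid: c = 1 -> 1 (e < 1); c = 0 -> -1 (e > 0); c = e -> 0
  for (p in seq(0.1, 0.9, by = 0.2)) {
    e <- p^2 + (1 - p)^2
    expect_equal(gegear_ci(1, p), 1)
    expect_equal(gegear_ci(0, p), -1)
    expect_equal(gegear_ci(e, p), 0)
  }
  # undefined denominator (c = e = 1) is flagged missing, not 0;
  # c = 0 with p = 0 is defined (e = 1) and gives -1
  expect_true(is.na(gegear_ci(1, 1)))
  expect_equal(gegear_ci(0, 0), -1)
  expect_error(gegear_ci(1.2, 0.5), class = "isobarrier_invalid_input")
})

test_that("CI is invariant to which form is focal", {
  for (p in seq(0.05, 0.95, by = 0.1)) {
    for (c_ in seq(0, 1, by = 0.25)) {
      a <- gegear_ci(c_, p)
      b <- gegear_ci(c_, 1 - p)
      expect_equal(a, b)
    }
  }
})

test_that("pollinator_success_pairs reproduces the published pink RI", {
  paper <- transition_table_from_counts(data.frame(
    from = c("white", "white", "pink", "pink"),
    to = c("white", "pink", "pink", "white"),
    count = c(370, 20, 64, 20)))
  pairs <- pollinator_success_pairs(paper)
  pink <- pairs[pairs$maternal_form == "pink", ]
  expect_equal(pink$conspecific, 64)
  expect_equal(pink$heterospecific, 20)
  expect_equal(round_half_up(pink$ri), 0.52)
  # note: the white direction evaluates to 0.90 from these counts
  white <- pairs[pairs$maternal_form == "white", ]
  expect_equal(round_half_up(white$ri), 0.90)

  none <- transition_table_from_counts(data.frame(
    from = c("white", "pink"), to = c("white", "pink"),
    count = c(10, 10)))
  p2 <- pollinator_success_pairs(none)
  expect_true(all(p2$ri == 1))

  zero <- transition_table_from_counts(data.frame(
    from = "white", to = "white", count = 0))
  expect_error(pollinator_success_pairs(zero),
               class = "isobarrier_undefined_ri")
})

test_that("species_ci_summary excludes undefined CIs and flags n = 1", {
  recs <- tibble::tibble(
    forager_id = c("a", "b", "c"),
    species = c("s1", "s1", "s2"),
    n_transitions = c(4L, 5L, 3L),
    c = c(1, 0, 1), p = c(0.5, 0.5, 0.5),
    e = 0.5, ci = c(1, -1, NA))
  s <- species_ci_summary(recs)
  s1 <- s[s$species == "s1", ]
  expect_equal(s1$mean_ci, 0)
  expect_equal(s1$n, 2L)
  s2 <- s[s$species == "s2", ]
  expect_equal(s2$n, 0L)
  expect_equal(s2$n_undefined, 1L)

  one <- species_ci_summary(tibble::tibble(
    forager_id = "a", species = "s", n_transitions = 2L,
    c = 0.5, p = 0.5, e = 0.5, ci = 0.3))
  expect_equal(one$sd_ci, 0)
  expect_equal(one$n, 1L)
})

test_that("mean CI increases with the stay probability kappa", {
  kappas <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(seq_along(kappas), function(i) {
    cfg <- simulation_config(seed = 500 + i, foraging = list(species = list(
      list(species = "sim", kappa = kappas[i], n_foragers = 150,
           bout_mean = 12))))
    recs <- forager_constancy(simulate_foraging(cfg))
    mean(recs$ci, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("availability-random foraging gives CI near zero at long bouts", {
  # the plug-in CI estimator has a negative O(1/bout length) bias, so
  # the random-choice null is recovered in the long-bout regime
  cfg <- simulation_config(seed = 77, foraging = list(species = list(
    list(species = "sim", kappa = 0, n_foragers = 150, bout_mean = 80))))
  recs <- forager_constancy(simulate_foraging(cfg))
  expect_lt(abs(mean(recs$ci, na.rm = TRUE)), 0.05)
})
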