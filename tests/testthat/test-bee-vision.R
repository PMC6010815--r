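test_that("resample_spectrum interpolates linearly without extrapolating", {
  g <- canonical_grid()
  s <- spectrum(g, rep(0.5, length(g)))
  expect_equal(resample_spectrum(s)$value, s$value)  # identity on grid

  fine <- seq(300, 700.37, by = 0.37)  # spectrometer-style increments
  s037 <- spectrum(fine, rep(0.25, length(fine)))
  expect_equal(resample_spectrum(s037)$value, rep(0.25, length(g)))

  # linear ramp preserved exactly at grid points
  ramp <- spectrum(seq(300, 700, by = 10), seq(0, 1, length.out = 41))
  out <- resample_spectrum(ramp)
  expect_equal(out$value, (g - 300) / 400, tolerance = 1e-12)

  short <- spectrum(seq(350, 700, 5), rep(1, 71))
  expect_error(resample_spectrum(short), class = "isobarrier_invalid_input")

  noisy <- spectrum(seq(300, 700, 5), c(-0.01, rep(0.2, 80)))
  expect_warning(out <- resample_spectrum(noisy), "clipped")
  expect_true(all(out$value >= 0))
})

test_that("pigment template peaks at lambda_max with value 1", {
  for (lm in c(344, 436, 544)) {
    s <- pigment_template(lm)
    expect_equal(max(s$value), 1)
    expect_lte(abs(s$wavelength[which.max(s$value)] - lm), 2)
  }
  # alpha-band half-maximum bandwidth: evaluate the template closed form
  s <- pigment_template(544)
  above <- s$wavelength[s$value >= 0.5]
  width <- max(above) - min(above)
  expect_gt(width, 60)   # rhodopsin alpha bands are ~80-110 nm wide
  expect_lt(width, 130)
  expect_error(pigment_template(250), class = "isobarrier_invalid_input")
})

test_that("quantum catches are von Kries normalised", {
  vm <- vision_model("honeybee")
  bg <- spectrum(vm$grid, vm$background)
  expect_equal(unname(quantum_catch(bg, vm)), c(1, 1, 1))
  twice <- spectrum(vm$grid, 2 * vm$background)
  expect_equal(unname(quantum_catch(twice, vm)), c(2, 2, 2))

  # doubling the illuminant changes nothing
  vm2 <- vision_model("honeybee",
                      illuminant = spectrum(vm$grid, 2 * vm$illuminant,
                                            "illuminant"))
  stim <- spectrum(vm$grid, seq(0.1, 0.9, length.out = length(vm$grid)))
  expect_equal(quantum_catch(stim, vm), quantum_catch(stim, vm2))
})

test_that("excitation and hexagon geometry", {
  expect_equal(receptor_excitation(0), 0)
  expect_equal(receptor_excitation(1), 0.5)
  expect_gt(receptor_excitation(1e6), 0.999)
  expect_error(receptor_excitation(-1), class = "isobarrier_invalid_input")

  expect_equal(unlist(hexagon_locus(0.5, 0.5, 0.5)[, c("x", "y")]),
               c(x = 0, y = 0))
  expect_equal(unlist(hexagon_locus(0, 0.999, 0)[, c("x", "y")]),
               c(x = 0, y = 0.999))
  l <- hexagon_locus(0, 0, 0.999)
  expect_equal(l$x, sqrt(3) / 2 * 0.999)
  expect_equal(l$y, -0.999 / 2)
  expect_error(hexagon_locus(1, 0.5, 0.5),
               class = "isobarrier_invalid_input")
})

test_that("scalar multiples of the background map to the origin", {
  vm <- vision_model("honeybee")
  for (k in c(0.25, 1, 3)) {
    stim <- spectrum(vm$grid, k * vm$background)
    loc <- hexagon_locus(receptor_excitation(quantum_catch(stim, vm)))
    expect_equal(loc$x, 0, tolerance = 1e-10)
    expect_equal(loc$y, 0, tolerance = 1e-10)
  }
})

test_that("joint stimulus/background rescaling leaves loci unchanged", {
  vm <- vision_model("honeybee")
  g <- vm$grid
  stim <- spectrum(g, 0.2 + 0.6 / (1 + exp(-(g - 550) / 30)))
  l1 <- hexagon_locus(receptor_excitation(quantum_catch(stim, vm)))
  # exact for any common positive factor
  for (k in c(0.1, 2, 25)) {
    vm2 <- vm
    vm2$background <- vm$background * k
    stim2 <- spectrum(g, stim$value * k)
    l2 <- hexagon_locus(receptor_excitation(quantum_catch(stim2, vm2)))
    expect_equal(l1$x, l2$x, tolerance = 1e-10)
    expect_equal(l1$y, l2$y, tolerance = 1e-10)
  }
  # a slowly varying spectral rescaling (an illuminant shift) is only
  # approximately discounted: the locus moves, but very little
  scale_fun <- 0.5 + (g - 300) / 800
  vm3 <- vm
  vm3$background <- vm$background * scale_fun
  stim3 <- spectrum(g, stim$value * scale_fun)
  l3 <- hexagon_locus(receptor_excitation(quantum_catch(stim3, vm3)))
  expect_lt(chromatic_distance(l1, l3), 0.01)
})

test_that("loci are bounded and distances satisfy metric properties", {
  set.seed(21)
  pts <- replicate(30, hexagon_locus(runif(1, 0, 0.99), runif(1, 0, 0.99),
                                     runif(1, 0, 0.99)),
                   simplify = FALSE)
  for (p in pts) {
    expect_lte(abs(p$x), sqrt(3) / 2)
    expect_lte(abs(p$y), 1)
  }
  for (i in 1:20) {
    tri <- sample(pts, 3)
    dab <- chromatic_distance(tri[[1]], tri[[2]])
    dba <- chromatic_distance(tri[[2]], tri[[1]])
    dac <- chromatic_distance(tri[[1]], tri[[3]])
    dcb <- chromatic_distance(tri[[3]], tri[[2]])
    expect_equal(dab, dba)
    expect_lte(dab, dac + dcb + 1e-12)
    expect_lte(dab, 2)
  }
  expect_equal(chromatic_distance(pts[[1]], pts[[1]]), 0)
})

test_that("adding green-band reflectance moves the locus toward +x", {
  vm <- vision_model("honeybee")
  g <- vm$grid
  base <- 0.3 + numeric(length(g))
  bumped <- base + 0.3 * exp(-((g - 544) / 25)^2)
  l0 <- hexagon_locus(receptor_excitation(
    quantum_catch(spectrum(g, base), vm)))
  l1 <- hexagon_locus(receptor_excitation(
    quantum_catch(spectrum(g, bumped), vm)))
  expect_gt(l1$x, l0$x)
})

test_that("discriminability applies the JND threshold", {
  d <- discriminable(c(0.21, 0.06, 0))
  expect_equal(d$discriminable, c(TRUE, FALSE, FALSE))
  expect_equal(d$margin, c(0.11, -0.04, -0.1))
  expect_error(discriminable(-0.1), class = "isobarrier_invalid_input")
})

test_that("both species models order synthetic colour types alike", {
  sp <- simulate_spectra(simulation_config(
    seed = 3, spectra = list(n = c(white = 3, pink = 3, intermediate = 3))))
  for (species in c("honeybee", "bumblebee")) {
    vm <- vision_model(species)
    loci <- hexagon_loci(sp, vm)
    dm <- chromatic_distance_matrix(loci)$distances
    wp <- mean(dm[grep("^white", rownames(dm)), grep("^pink", colnames(dm))])
    wi <- mean(dm[grep("^white", rownames(dm)),
                  grep("^intermediate", colnames(dm))])
    expect_gt(wp, wi)
    expect_gt(wp, 0.1)
  }
})
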