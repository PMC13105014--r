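test_that("generation is deterministic and byte-reproducible", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  sp <- function() fibril_spec(-1.75, 2.34, "pseudo-21", n_layers = 2,
                               noise_sigma = 0.2, seed = 7)
  write_fibril_model(generate_fibril(sp()), f1)
  write_fibril_model(generate_fibril(sp()), f2)
  expect_identical(readLines(f1), readLines(f2))

  ## a different seed changes the noise draws
  f3 <- withr::local_tempfile(fileext = ".pdb")
  write_fibril_model(generate_fibril(
    fibril_spec(-1.75, 2.34, "pseudo-21", n_layers = 2,
                noise_sigma = 0.2, seed = 8)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))

  ## the generator does not disturb the global RNG stream
  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(generate_fibril(sp())); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("random specs round-trip through helical refitting to 1e-6", {
  set.seed(606)
  for (i in 1:20) {
    sym <- sample(c("C2", "pseudo-21", "C1"), 1)
    if (sym == "pseudo-21") {
      f <- stats::runif(1, 0.5, 3) * sample(c(-1, 1), 1)
      tw <- f + 180 * sign(f)
      ri <- stats::runif(1, 2.3, 2.5)
    } else if (sym == "C2") {
      tw <- stats::runif(1, 0.5, 6) * sample(c(-1, 1), 1)
      ri <- stats::runif(1, 4.6, 4.9)
    } else {
      tw <- stats::runif(1, 1, 8) * sample(c(-1, 1), 1)
      ri <- stats::runif(1, 9, 10)
    }
    m <- generate_fibril(fibril_spec(tw, ri, sym, n_layers = 3, seed = i))
    m$subunit <- m$layer <- m$axis <- NULL
    hp <- fit_helical_params(m)
    expect_equal(hp$symmetry, sym)
    expect_equal(hp$twist, tw, tolerance = 1e-6)
    expect_equal(hp$rise, ri, tolerance = 1e-6)
  }
})

test_that("width-profile minima spacing matches the analytic cross-over", {
  for (d in c(24, 44)) {
    nl <- ceiling(3 * d * 10 / 4.7)
    m <- generate_fibril(fibril_spec(twist_from_crossover(d, 4.7), 4.7, "C1",
                                     n_layers = nl, n_subunits = 1,
                                     atoms = "ca", offset = 0))
    wp <- width_profile(m)
    expect_false(wp$untwisted)
    expect_equal(wp$spacing_nm, d, tolerance = 0.05 * d)
  }
})

test_that("untwisted fibrils produce no width minima", {
  m <- generate_fibril(fibril_spec(180, 4.7, "pseudo-21", n_layers = 60,
                                   atoms = "ca"))
  wp <- width_profile(m)
  expect_true(wp$untwisted)
  expect_true(is.na(wp$spacing_nm))
})

test_that("end spacing of generated fibrils matches the strain model", {
  for (cs in list(c(L = 5.3, d = 25), c(L = 7.3, d = 25), c(L = 4, d = 60))) {
    L <- cs[["L"]]; d <- cs[["d"]]
    npts <- max(5, round(L * 10 / 3.8))
    tpl <- cbind(seq(-L * 10 / 2, L * 10 / 2, length.out = npts), 0)
    m <- generate_fibril(fibril_spec(twist_from_crossover(d, 4.8), 4.8, "C1",
                                     n_layers = 2, n_subunits = 1,
                                     template = tpl, offset = 0, atoms = "ca",
                                     strand_plan = list()))
    ca <- function(ch, rn) as.numeric(
      m$atoms[m$atoms$chain == ch & m$atoms$resno == rn, c("x", "y", "z")])
    meas <- sqrt(sum((ca("A", 1) - ca("B", 1))^2)) / 10
    expect_equal(meas, end_spacing(L, d), tolerance = 0.01 * end_spacing(L, d))
    meas2 <- sqrt(sum((ca("A", npts) - ca("B", npts))^2)) / 10
    expect_equal(meas2, end_spacing(L, d), tolerance = 0.01 * end_spacing(L, d))
  }
})

test_that("mirroring flips the sign of the fitted twist", {
  m <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3))
  mm <- m
  mm$atoms$x <- -mm$atoms$x
  mm$subunit <- mm$layer <- mm$axis <- NULL
  expect_equal(fit_helical_params(mm)$twist, 3.55, tolerance = 1e-6)
})

test_that("strand-detection recall is non-increasing in noise", {
  recall <- vapply(c(0, 0.15, 0.3, 1.0), function(s) {
    m <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                     noise_sigma = s, seed = 5))
    strand_pr(beta_strand_segments(m), list(c(14, 22), c(30, 36)))[["recall"]]
  }, numeric(1))
  expect_equal(recall[1], 1)
  expect_true(all(diff(recall) <= 0))
})

test_that("invalid specs are rejected", {
  expect_error(fibril_spec(-3.55, -1, "C2"), "positive")
  expect_error(fibril_spec(-3.55, 4.69, "C2", n_subunits = 1), "single-subunit")
  expect_error(fibril_spec(-3.55, 4.69, "C2", strand_plan = list(c(1, 5))),
               "amide hydrogen")
  expect_error(fibril_spec(-3.55, 4.69, "C2",
                           template = matrix(0, 5, 3)), "n x 2")
})
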