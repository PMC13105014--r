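test_that("fold_twist reduces screw twists to net cross-section rotation", {
  expect_equal(fold_twist(-181.75), -1.75)
  expect_equal(fold_twist(179.53), -0.47)
  expect_identical(fold_twist(180), 0)
  expect_equal(fold_twist(-180), 0)
  expect_error(fold_twist(NaN), "finite")
  expect_error(fold_twist(Inf), "finite")

  grid <- seq(-721, 721, by = 0.37)
  f <- fold_twist(grid)
  expect_true(all(f > -90 & f <= 90))
  expect_equal(fold_twist(f), f)          # idempotent
})

test_that("cross-over distance reproduces the worked values and handles untwisted stacks", {
  expect_equal(crossover_distance(-181.75, 2.34), 24.07, tolerance = 1e-3)
  expect_equal(crossover_distance(-5.24, 9.40), 32.3, tolerance = 1e-2)
  expect_equal(crossover_distance(179.75, 2.44), 175.7, tolerance = 1e-3)
  expect_identical(crossover_distance(180, 2.4), Inf)
  expect_error(crossover_distance(-3.55, -1), "positive")

  hp <- helical_params(-181.75, 2.34, "pseudo-21", handedness = "right")
  expect_equal(crossover_distance(hp), 24.07, tolerance = 1e-3)
})

test_that("cross-over distance is invariant under twist +/- 360 and sign flip", {
  tw <- c(-181.75, -3.55, -5.24, 179.53, 0.79)
  for (t0 in tw) {
    d0 <- crossover_distance(t0, 2.4)
    expect_equal(crossover_distance(t0 + 360, 2.4), d0)
    expect_equal(crossover_distance(t0 - 360, 2.4), d0)
    expect_equal(crossover_distance(-t0, 2.4), d0)
  }
})

test_that("every published polymorph row reproduces its printed integer cross-over", {
  tab <- crossover_report(ab40_polymorphs())
  expect_equal(nrow(tab), 14)
  expect_true(all(tab$consistent))
  expect_equal(tab$crossover_round_nm,
               c(24, 24, 32, 44, 36, 55, 111, 93, 38, 43, 110, 90, 176, 130))
})

test_that("twist_from_crossover inverts the forward computation", {
  expect_equal(twist_from_crossover(24.07, 2.34, screw = TRUE), -181.75,
               tolerance = 1e-4)
  expect_equal(abs(twist_from_crossover(23.78, 4.69)), 3.55, tolerance = 1e-3)
  expect_equal(twist_from_crossover(Inf, 2.4), 0)
  expect_equal(twist_from_crossover(Inf, 2.4, screw = TRUE), -180)
  expect_error(twist_from_crossover(-5, 2.4), "positive")
  expect_error(twist_from_crossover(10, 0), "positive")

  for (d in c(5, 17.3, 24.07, 99.9, 500)) {
    for (scr in c(TRUE, FALSE)) {
      tw <- twist_from_crossover(d, 2.4, screw = scr)
      expect_equal(crossover_distance(tw, 2.4), d, tolerance = 1e-9 * d)
    }
  }
})

test_that("symmetry operators realize the symmetry class", {
  c2 <- symmetry_operators(helical_params(-3.55, 4.69, "C2"), 1)
  expect_length(c2, 2)
  expect_equal(c2[[1]]$R, diag(3))
  expect_equal(c2[[2]]$angle_deg, 180)
  expect_equal(c2[[2]]$t, c(0, 0, 0))

  c1 <- symmetry_operators(helical_params(-5.24, 9.40, "C1"), 3)
  expect_equal(vapply(c1, `[[`, numeric(1), "translation"), c(0, 9.40, 18.80))
  expect_equal(vapply(c1, `[[`, numeric(1), "angle_deg"), c(0, -5.24, -10.48))

  p21 <- symmetry_operators(helical_params(-181.75, 2.34, "pseudo-21"), 2)
  expect_equal(vapply(p21, `[[`, character(1), "subunit"), c("A", "B", "A", "B"))
  gen <- p21[[2]]
  net <- compose_transforms(gen, gen)
  expect_equal(net$angle_deg, -363.5)
  expect_equal(net$translation, 4.68)
  ## closure: the composed transform equals the stored two-step operator
  expect_equal(net$R, p21[[3]]$R, tolerance = 1e-12)
  expect_equal(net$t, p21[[3]]$t, tolerance = 1e-12)

  expect_error(helical_params(-3.55, 4.69, "C7"), "symmetry")
})

test_that("polymorph tables round-trip through TSV and JSON", {
  tab <- ab40_polymorphs()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_polymorph_table(tab, tsv)
  write_polymorph_table(tab, js)
  t1 <- read_polymorph_table(tsv)
  t2 <- read_polymorph_table(js)
  expect_equal(t1$twist_deg, tab$twist_deg)
  expect_equal(t2$twist_deg, tab$twist_deg)
  expect_equal(t1$symmetry, tab$symmetry)
  expect_error(read_polymorph_table(withr::local_tempfile()), "no such file")
})
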