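test_that("PDB write/read round-trips coordinates and identity", {
  m <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fibril_model(m, f)
  m2 <- read_fibril_model(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_identical(m2$atoms$chain, m$atoms$chain)
  expect_identical(m2$atoms$resno, m$atoms$resno)
  expect_identical(m2$atoms$resid, m$atoms$resid)
  expect_identical(m2$atoms$elety, m$atoms$elety)
  expect_lt(max(abs(m2$atoms$x - m$atoms$x)), 1e-3)
  expect_lt(max(abs(m2$atoms$y - m$atoms$y)), 1e-3)
  expect_lt(max(abs(m2$atoms$z - m$atoms$z)), 1e-3)
})

test_that("empty or malformed files raise parse errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    synthetic", "END"), f)
  expect_error(read_fibril_model(f))
  expect_error(read_fibril_model(withr::local_tempfile(fileext = ".pdb")),
               "no such file")
  expect_error(fibril_model(data.frame(model = 1)), "missing column")
})

test_that("organization is inferred from coordinates alone", {
  ## pseudo-2_1: 6 chains -> 3 layers x 2 subunits, axis within 0.5 deg
  m <- generate_fibril(fibril_spec(-181.75, 2.34, "pseudo-21", n_layers = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fibril_model(m, f)
  m2 <- infer_layers_and_subunits(read_fibril_model(f))
  expect_equal(sort(as.vector(table(m2$subunit))), c(3L, 3L))
  for (s in unique(m2$subunit)) {
    expect_equal(sort(unname(m2$layer[names(m2$subunit)[m2$subunit == s]])), 1:3)
  }
  axis_err <- acos(min(1, abs(m2$axis$v[3]))) * 180 / pi
  expect_lt(axis_err, 0.5)

  ## C2: two subunits related by a two-fold, per-layer rise recovered
  mc <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3))
  mc$subunit <- mc$layer <- mc$axis <- NULL
  mc <- infer_layers_and_subunits(mc)
  hp <- fit_helical_params(mc)
  expect_equal(hp$symmetry, "C2")
  expect_equal(hp$rise, 4.69, tolerance = 1e-9)
  det <- attr(hp, "details")
  expect_equal(abs(det$inter_subunit_angle), 180, tolerance = 1e-6)

  ## untwisted stack: axis equals the stacking direction
  mu <- generate_fibril(fibril_spec(180, 2.4, "pseudo-21", n_layers = 3))
  mu$subunit <- mu$layer <- mu$axis <- NULL
  mu <- infer_layers_and_subunits(mu)
  expect_equal(abs(mu$axis$v[3]), 1, tolerance = 1e-9)

  ## single chain: warning and trivial assignment
  one <- generate_fibril(fibril_spec(-3.55, 4.69, "C1", n_layers = 1,
                                     n_subunits = 1))
  one$subunit <- one$layer <- one$axis <- NULL
  expect_warning(r <- infer_layers_and_subunits(one), "single")
  expect_equal(unname(r$layer), 1L)
})

test_that("helical parameters are recovered exactly from noise-free models", {
  cases <- list(
    list(tw = -3.55, ri = 4.69, sym = "C2"),
    list(tw = 2.1, ri = 4.76, sym = "C2"),
    list(tw = -181.75, ri = 2.34, sym = "pseudo-21"),
    list(tw = 181.18, ri = 2.38, sym = "pseudo-21"),
    list(tw = -5.24, ri = 9.40, sym = "C1")
  )
  for (cs in cases) {
    m <- generate_fibril(fibril_spec(cs$tw, cs$ri, cs$sym, n_layers = 3))
    m$subunit <- m$layer <- m$axis <- NULL
    hp <- fit_helical_params(m)
    expect_equal(hp$symmetry, cs$sym)
    expect_equal(hp$twist, cs$tw, tolerance = 1e-6)
    expect_equal(hp$rise, cs$ri, tolerance = 1e-6)
  }
  expect_error(fit_helical_params(generate_fibril(
    fibril_spec(-3.55, 4.69, "C1", n_layers = 1, n_subunits = 1))),
    "insufficient")
})

test_that("a C1 fibril with inequivalent subunits is classified C1", {
  m <- generate_fibril(fibril_spec(-5.24, 9.40, "C1", n_layers = 3))
  m$subunit <- m$layer <- m$axis <- NULL
  hp <- fit_helical_params(m)
  expect_equal(hp$symmetry, "C1")
  expect_equal(hp$molecules_per_repeat, 2L)
  expect_equal(hp$twist, -5.24, tolerance = 1e-6)
  expect_equal(hp$rise, 9.40, tolerance = 1e-6)
})

test_that("fit error grows gracefully with coordinate noise", {
  errs <- vapply(c(0, 0.1, 0.25, 0.5), function(s) {
    m <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3,
                                     noise_sigma = s, seed = 11))
    m$subunit <- m$layer <- m$axis <- NULL
    hp <- fit_helical_params(m, same_rmsd = 2.0)
    abs(hp$twist + 3.55)
  }, numeric(1))
  expect_lt(errs[1], 1e-8)
  expect_true(all(diff(errs) >= 0))
  expect_lt(errs[4], 0.5)
})

test_that("cross-over from refitted parameters matches the generating distance", {
  for (d in c(20, 45, 90, 150)) {
    tw <- twist_from_crossover(d, 4.69)
    m <- generate_fibril(fibril_spec(tw, 4.69, "C2", n_layers = 3))
    m$subunit <- m$layer <- m$axis <- NULL
    dd <- crossover_distance(fit_helical_params(m))
    expect_equal(dd, d, tolerance = 0.01 * d)
  }
})
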