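test_that("torsions are recovered exactly from torsion-built chains", {
  combos <- list(c(-130, 130), c(-57, -47), c(120, -120), c(-75, 145))
  for (cc in combos) {
    ch <- build_chain_from_torsions(phi = rep(cc[1], 7), psi = rep(cc[2], 7))
    tt <- compute_torsions(ch)
    expect_true(is.na(tt$phi[1]))
    expect_true(is.na(tt$psi[nrow(tt)]))
    expect_equal(tt$phi[-1], rep(cc[1], 6), tolerance = 1e-6)
    expect_equal(tt$psi[-nrow(tt)], rep(cc[2], 6), tolerance = 1e-6)
  }
  ## a glycine-like left-handed sign flip comes back with correct signs
  ch <- build_chain_from_torsions(phi = c(-130, 120, -130), psi = c(130, -120, 130))
  tt <- compute_torsions(ch)
  expect_equal(tt$phi[2], 120, tolerance = 1e-6)
  expect_equal(tt$psi[2], -120, tolerance = 1e-6)
})

test_that("collinear backbone geometry yields NA torsions without crashing", {
  atoms <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(model = 1L, chain = "A", resno = i, resid = "ALA",
               elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
               x = (3 * (i - 1) + 0:2) * 1.4, y = 0, z = 0,
               stringsAsFactors = FALSE)
  }))
  m <- fibril_model(atoms)
  tt <- compute_torsions(m)
  expect_true(all(is.na(tt$phi)))
  expect_true(all(is.na(tt$psi)))
})

test_that("dihedral agrees with the independent four-point oracle", {
  set.seed(202)
  worst <- 0
  for (i in 1:300) {
    p <- matrix(stats::rnorm(12, 0, 5), 4, 3)
    a <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    b <- dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ])
    if (is.na(a)) { expect_true(is.na(b)); next }
    worst <- max(worst, abs(circular_diff(a, b)))
  }
  expect_lt(worst, 1e-9)
})

test_that("beta-strand deviation windows are circular and boundary-inclusive", {
  tt <- data.frame(model = 1L, chain = "A", subunit = "A",
                   resno = 1:5, resid = "ALA",
                   phi = c(-130, 120, -159.9, -161, NA),
                   psi = c(130, -120, 100.1, 130, 140))
  class(tt) <- c("torsion_table", "data.frame")
  dev <- beta_deviation(tt)
  expect_false(dev$deviates[dev$resno == 1])              # window center
  expect_true(dev$phi_dev[dev$resno == 2])                # sign-flipped phi
  expect_false(dev$deviates[dev$resno == 3])              # on the boundary
  expect_true(dev$phi_dev[dev$resno == 4])                # just outside
  expect_true(is.na(dev$phi_dev[dev$resno == 5]))         # undefined excluded
})

test_that("hydrogen bonds in a cross-beta stack alternate sides along strands", {
  m <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3))
  hb <- detect_hbonds(m)
  expect_gt(nrow(hb), 0)
  ## the interior chain of subunit A donates and accepts at every designed
  ## strand residue
  sc <- names(m$subunit)[m$subunit == "A"]
  mid <- sc[m$layer[sc] == 2]
  plan_res <- c(14:22, 30:36)
  don <- unique(hb$donor_resno[hb$donor_chain == mid])
  acc <- unique(hb$acceptor_resno[hb$acceptor_chain == mid])
  expect_true(all(plan_res %in% don))
  expect_true(all(plan_res %in% acc))
  ## donation side alternates residue to residue along each strand
  side_of <- vapply(14:22, function(r) {
    s <- unique(hb$side[hb$donor_chain == mid & hb$donor_resno == r])
    expect_length(s, 1)
    s
  }, integer(1))
  expect_true(all(abs(diff(side_of)) == 2))
  ## turn residues stay out of axial register
  expect_false(any(25:28 %in% intersect(don, acc)))
})

test_that("hydrogen bonds vanish for pulled-apart or isolated chains", {
  apart <- generate_fibril(fibril_spec(-0.8, 8.0, "C2", n_layers = 3))
  expect_equal(nrow(detect_hbonds(apart)), 0)
  single <- generate_fibril(fibril_spec(-0.8, 4.69, "C1", n_layers = 1,
                                        n_subunits = 1))
  single$axis <- list(v = c(0, 0, 1), origin = c(0, 0, 0))
  expect_equal(nrow(detect_hbonds(single)), 0)
})

test_that("the dssp-energy criterion finds the same designed strand bonds", {
  m <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3))
  hb_g <- detect_hbonds(m, mode = "geometric")
  hb_d <- detect_hbonds(m, mode = "dssp")
  key <- function(h) paste(h$donor_chain, h$donor_resno, h$acceptor_chain,
                           h$acceptor_resno)
  expect_gt(length(intersect(key(hb_g), key(hb_d))), 0.8 * nrow(hb_g))
})

test_that("strand segments recover the designed plan exactly at zero noise", {
  plan <- list(c(14, 22), c(30, 36))
  for (sym in c("C2", "pseudo-21")) {
    tw <- if (sym == "C2") -0.8 else -180.4
    ri <- if (sym == "C2") 4.69 else 2.345
    m <- generate_fibril(fibril_spec(tw, ri, sym, n_layers = 3,
                                     strand_plan = plan))
    segs <- beta_strand_segments(m)
    for (su in unique(segs$subunit)) {
      pr <- strand_pr(segs, plan, su)
      expect_equal(unname(pr), c(1, 1))
    }
    expect_equal(segs[segs$subunit == "A", "start"], c(14, 30))
    expect_equal(segs[segs$subunit == "A", "end"], c(22, 36))
  }
})

test_that("segments require three residues and alternating sides on re-check", {
  plan <- list(c(14, 16), c(30, 36))
  m <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                   strand_plan = plan))
  segs <- beta_strand_segments(m)
  expect_true(all(segs$length >= 3))
  expect_equal(segment_residues(segs, "A"), c(14:16, 30:36))

  ## removing one carbonyl leaves a two-residue stretch: below the minimum
  m2 <- m
  m2$atoms <- m2$atoms[!(m2$atoms$resno == 16 & m2$atoms$elety == "O"), ]
  segs2 <- beta_strand_segments(m2)
  expect_equal(segment_residues(segs2, "A"), 30:36)

  ## alternation re-check from the carbonyl directions
  cs <- crossbeta:::carbonyl_sides(m, model = 1)
  sc <- names(m$subunit)[m$subunit == "A"]
  mid <- sc[m$layer[sc] == 2]
  for (i in seq_len(nrow(segs))) {
    if (segs$subunit[i] != "A") next
    sides <- sign(cs$axial[cs$chain == mid &
                           cs$resno %in% segs$start[i]:segs$end[i]])
    expect_true(all(abs(diff(sides)) == 2))
  }
  ## designed strands shorter than 3 residues are rejected by the spec
  expect_error(fibril_spec(-0.8, 4.69, "C2", strand_plan = list(c(14, 15))),
               "length >= 3")
})

test_that("major axis tilt and herringbone angle match construction", {
  flat <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3))
  expect_lt(major_axis(flat, "A", c(1, 40))$tilt_deg, 1e-6)

  tilted <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                        tilt_deg = 3.5))
  ma <- major_axis(tilted, "A", c(1, 40))
  expect_equal(ma$tilt_deg, 3.5, tolerance = 0.1)
  expect_equal(herringbone_angle(tilted, c(1, 40)), 7.0, tolerance = 0.01)

  ## exact two-fold images (single layer): exactly twice the tilt
  exact <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 1,
                                       tilt_deg = 3.5))
  expect_equal(herringbone_angle(exact, c(1, 40)), 7.0, tolerance = 1e-6)
  expect_lt(herringbone_angle(flat, c(1, 40)), 1e-6)

  expect_error(major_axis(flat, "A", c(1, 99)), "insufficient")
  single <- generate_fibril(fibril_spec(-0.8, 4.69, "C1", n_layers = 2,
                                        n_subunits = 1))
  expect_error(herringbone_angle(single, c(1, 40)), "two subunits")
})

test_that("contact maps are symmetric, monotone in cutoff, and empty when apart", {
  m <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3))
  cm5 <- contact_map(m, cutoff = 5)
  cm7 <- contact_map(m, cutoff = 7)
  expect_true(all(cm5$dist <= 5))
  k <- function(cm) paste(cm$resno_a, cm$resno_b)
  expect_true(all(k(cm5) %in% k(cm7)))          # monotone in cutoff
  ## symmetric under swapping the subunit labels
  ms <- m
  ms$subunit[ms$subunit == "A"] <- "Z"
  ms$subunit[ms$subunit == "B"] <- "A"
  ms$subunit[ms$subunit == "Z"] <- "B"
  cm5s <- contact_map(ms, cutoff = 5)
  expect_setequal(k(cm5s), paste(cm5$resno_b, cm5$resno_a))
  expect_equal(sort(cm5s$dist), sort(cm5$dist))

  far <- generate_fibril(fibril_spec(-3.55, 4.69, "C2", n_layers = 3,
                                     offset = 30))
  expect_equal(nrow(contact_map(far, cutoff = 5)), 0)
})

test_that("the designed K28-D23 salt bridge is detected at its built distance", {
  m <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                   salt_dist = 3.3))
  sb <- salt_bridge(m)
  expect_true(sb$present)
  expect_equal(sb$dist, 3.3, tolerance = 1e-6)

  far <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                     salt_dist = 6.0))
  expect_false(salt_bridge(far)$present)

  bb <- generate_fibril(fibril_spec(-0.8, 4.69, "C2", n_layers = 3,
                                    atoms = "backbone"))
  expect_warning(ind <- salt_bridge(bb), "missing")
  expect_true(is.na(ind$present))
})
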