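# Strand assignment, axis/ellipse fits, shear measurement, superposition,
# repeat symmetry, face enrichment.

test_that("assign_strands recovers the designed strands", {
  st <- ovoid_strands()
  expect_equal(st$n_strands, 8L)
  bp <- make_ovoid_blueprint()
  detected <- table(st$residues$strand)
  expect_true(all(as.integer(detected) >= strand_lengths(bp) - 1))
})

test_that("assign_strands errors on helix-only input and honours overrides", {
  m <- ovoid_model()
  helices <- m[m$element == "helix", ]
  expect_error(assign_strands(ovoidtim:::as_barrel_model(helices)), "barrel error")
  ov <- tibble::tibble(residue = 1:10, strand = rep(1:2, each = 5))
  st <- assign_strands(m, override = ov)
  expect_equal(st$residues$strand, ov$strand)
})

test_that("deleting a strand loses exactly one detected strand", {
  m <- make_decoy(ovoid_model(), "deleted_strand", strand = 3)
  st <- assign_strands(m)
  expect_equal(st$n_strands, 7L)
})

test_that("measured shear equals the generating blueprint's shear on all presets", {
  expect_equal(measure_shear_from_structure(ovoid_model(), ovoid_strands()), 8L)
  expect_equal(measure_shear_from_structure(circular_model(), circular_strands()), 8L)
  expect_equal(measure_shear_from_structure(zero_shear_model()), 0L)
  expect_equal(measure_shear_from_structure(porin_model()), 8L)
})

test_that("an open barrel raises an error", {
  m <- make_decoy(ovoid_model(), "deleted_strand", strand = 5)
  st <- assign_strands(m)
  expect_error(measure_shear_from_structure(m, st), "open barrel")
})

test_that("the fitted axis lies along the construction axis and is equivariant", {
  m <- ovoid_model()
  st <- ovoid_strands()
  ax <- fit_barrel_axis(m, st)
  angle <- acos(min(abs(sum(ax$direction * c(0, 0, 1))), 1)) * 180 / pi
  expect_lt(angle, 2)
  R <- random_rotation(7)
  m2 <- transform_model(m, R, c(5, -3, 11))
  ax2 <- fit_barrel_axis(m2, st)
  expect_lt(acos(min(abs(sum(ax2$direction * (R %*% ax$direction))), 1)) * 180 / pi, 1e-4)
})

test_that("the axis survives coordinate noise", {
  angs <- vapply(1:5, function(s) {
    m <- make_decoy(ovoid_model(), "noise", sigma = 0.3, seed = s)
    ax <- fit_barrel_axis(m, ovoid_strands())
    acos(min(abs(sum(ax$direction * c(0, 0, 1))), 1)) * 180 / pi
  }, numeric(1))
  expect_true(all(angs < 5))
})

test_that("face labels put the long strand pairs on the flat major faces", {
  fo <- fit_cross_section(ovoid_model(), ovoid_strands())
  faces <- fo$strands$face[order(fo$strands$strand)]
  expect_equal(faces, c("minor", "minor", "major", "major",
                        "minor", "minor", "major", "major"))
  expect_equal(sum(faces == "major"), 4L)
})

test_that("shape fits are invariant to rigid motion", {
  m <- ovoid_model()
  st <- ovoid_strands()
  f1 <- fit_cross_section(m, st)
  m2 <- transform_model(m, random_rotation(3), c(-8, 2, 4))
  f2 <- fit_cross_section(m2, assign_strands(m2))
  expect_equal(f2$eccentricity, f1$eccentricity, tolerance = 1e-4)
  expect_equal(f2$semi_major_a, f1$semi_major_a, tolerance = 1e-3)
  expect_equal(measure_shear_from_structure(m2), 8L)
})

test_that("eccentricity follows from the fitted semi-axes", {
  f <- fit_cross_section(ovoid_model(), ovoid_strands())
  expect_equal(f$eccentricity,
               sqrt(1 - (f$semi_minor_b / f$semi_major_a)^2))
})

test_that("superpose handles identity, rigid motion and noise scaling", {
  set.seed(11)
  x <- matrix(stats::rnorm(600), ncol = 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  R <- random_rotation(5)
  y <- sweep(x %*% t(R), 2, c(3, -1, 7), `+`)
  expect_lt(superpose(y, x)$rmsd, 1e-6)
  sup <- superpose(y, x)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)

  # Monte-Carlo: iid Gaussian noise per axis gives RMSD ~ sigma * sqrt(3)
  sig <- 0.4
  rmsds <- vapply(1:10, function(s) {
    set.seed(100 + s)
    noisy <- x + matrix(stats::rnorm(600, sd = sig), ncol = 3)
    superpose(noisy, x)$rmsd
  }, numeric(1))
  expect_lt(abs(stats::median(rmsds) - sig * sqrt(3)) / (sig * sqrt(3)), 0.10)
  expect_error(superpose(x[1:10, ], x), "length")
})

test_that("superpose agrees with an independent reference implementation", {
  set.seed(21)
  a <- matrix(stats::rnorm(90), ncol = 3)
  b <- matrix(stats::rnorm(90), ncol = 3)
  ours <- superpose(a, b)$rmsd
  ref <- bio3d::rmsd(as.vector(t(b)), as.vector(t(a)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("repeat symmetry RMSD reflects injected asymmetry", {
  m <- ovoid_model()
  expect_lt(repeat_symmetry_rmsd(m, 114), 0.1)
  expect_error(repeat_symmetry_rmsd(m, 100), "2 \\* residues_per_repeat")
  # noise on repeat 2 only
  sig <- 0.5
  rmsds <- vapply(1:5, function(s) {
    set.seed(200 + s)
    m2 <- m
    idx <- 115:228
    rows <- match(idx, m2$residue)
    for (cc in paste0("ca_", c("x", "y", "z")))
      m2[[cc]][rows] <- m2[[cc]][rows] + stats::rnorm(114, sd = sig)
    repeat_symmetry_rmsd(m2, 114)
  }, numeric(1))
  expect_lt(abs(stats::median(rmsds) - sig * sqrt(3)) / (sig * sqrt(3)), 0.12)
})

test_that("small-residue enrichment flags designed minor-face packing", {
  bp <- make_ovoid_blueprint()
  strips <- enumerate_cbeta_strips(bp)
  m <- ovoid_model()
  faces <- fit_cross_section(m, ovoid_strands())$strands

  res <- small_residue_enrichment(m, strips, faces, n_perm = 500, seed = 4)
  expect_lt(res$mean_minor, res$mean_all)

  # extreme case: Ala at every minor position, Phe elsewhere
  m2 <- m
  minor_strands <- faces$strand[faces$face == "minor"]
  strip_minor <- strips$residue[strips$strand %in% minor_strands]
  m2$aa[match(strips$residue, m2$residue)] <- "F"
  m2$aa[match(strip_minor, m2$residue)] <- "A"
  res2 <- small_residue_enrichment(m2, strips, faces, n_perm = 1000, seed = 4)
  expect_lt(res2$difference, 0)
  expect_lt(res2$p_value, 0.01)

  # homopolymer: zero difference
  m3 <- m
  m3$aa <- rep("V", nrow(m3))
  res3 <- small_residue_enrichment(m3, strips, faces, n_perm = 100, seed = 1)
  expect_equal(res3$difference, 0)
})

test_that("the permutation p-value matches a tiny exhaustive oracle", {
  # 4 strip positions, 2 on the minor face; volumes distinguish all labels
  strips <- tibble::tibble(strip = 1L, strand = c(1L, 1L, 2L, 2L),
                           local = 1:4, residue = 1:4)
  faces <- tibble::tibble(strand = c(1L, 2L), face = c("minor", "major"))
  m <- toy_model(c("A", "A", "F", "F"))
  res <- small_residue_enrichment(m, strips, faces, n_perm = 2000, seed = 9)
  # exhaustive: choose(4,2)=6 assignments of the two Ala to minor slots
  vols <- residue_volumes()[c("A", "A", "F", "F")]
  combos <- utils::combn(4, 2)
  diffs <- apply(combos, 2, function(ix) {
    v <- vols
    mean(v[ix]) - mean(v)
  })
  p_exact <- mean(diffs <= res$difference)
  expect_lt(abs(res$p_value - p_exact), 0.05)
})
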