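# Position classification and the iterative-enrichment design loop.

test_that("classification assigns core strand positions to the hydrophobic class", {
  m <- ovoid_model()
  cls <- classify_positions(m, n_points = 240)
  core <- m$residue[m$element == "strand" & m$facing == "core"]
  expect_true(all(cls$class[match(core, cls$residue)] == "hydrophobic"))
  expect_setequal(unique(cls$class),
                  intersect(c("hydrophobic", "boundary", "solvent_exposed"),
                            unique(cls$class)))
  expect_equal(nrow(cls), nrow(m))
})

test_that("an extended isolated chain is fully solvent exposed", {
  m <- toy_model(rep("V", 8))
  m$element <- NA_character_
  cls <- classify_positions(m, n_points = 480)
  expect_true(all(cls$class == "solvent_exposed"))
})

test_that("classification overrides pass through verbatim", {
  ov <- tibble::tibble(residue = 1:5,
                       class = c("hydrophobic", "boundary", "boundary",
                                 "solvent_exposed", "hydrophobic"))
  expect_identical(classify_positions(ovoid_model(), override = ov), ov)
})

test_that("trajectories are deterministic under seed and independent across sub-seeds", {
  m <- ovoid_model()[1:12, ]
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  null_e <- function(s) 0
  t1 <- run_trajectories(m, cls, null_e, n_traj = 10, seed = 4,
                         steps_per_position = 5)
  t2 <- run_trajectories(m, cls, null_e, n_traj = 10, seed = 4,
                         steps_per_position = 5)
  expect_identical(t1, t2)
  t3 <- run_trajectories(m, cls, null_e, n_traj = 10, seed = 5,
                         steps_per_position = 5)
  expect_false(identical(t1$sequence, t3$sequence))
})

test_that("a strongly position-preferring energy dominates the trajectories", {
  m <- ovoid_model()[1:4, ]
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  target_row <- 2
  e <- function(s) ifelse(s[target_row] == "A", -10, 0)
  tr <- run_trajectories(m, cls, e, n_traj = 100, seed = 1,
                         steps_per_position = 30)
  picked <- substr(tr$sequence, target_row, target_row)
  # Boltzmann at T=1: p(A) = e^10 / (e^10 + 5) ~ 1
  expect_gte(mean(picked == "A"), 0.95)
})

test_that("null-energy trajectories are uniform over the allowed alphabet", {
  m <- ovoid_model()[1:2, ]
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  alpha <- stats::setNames(rep(list(c("A", "V", "I", "L")), 2),
                           as.character(m$residue))
  tr <- run_trajectories(m, cls, function(s) 0, n_traj = 1000, seed = 11,
                         alphabets = alpha, steps_per_position = 20)
  for (p in 1:2) {
    counts <- table(factor(substr(tr$sequence, p, p), levels = alpha[[1]]))
    expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  }
})

test_that("profiling counts frequencies exactly (hand-countable oracle)", {
  seqs <- c("AVL", "AVL", "AIL", "GVL", "AVL")
  pr <- profile_and_restrict(seqs)
  p1 <- pr$profile[pr$profile$position == "1", ]
  expect_equal(p1$freq[p1$aa == "A"], 0.8)
  expect_equal(p1$freq[p1$aa == "G"], 0.2)
  p2 <- pr$profile[pr$profile$position == "2", ]
  expect_equal(sort(p2$aa), c("I", "V"))
  expect_equal(pr$alphabets[["2"]], c("V", "I")[order(c("V", "I"))] |>
                 sort() |> intersect(c("I", "V")))
  sums <- tapply(pr$profile$freq, pr$profile$position, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("alphabets never grow and collapse on unanimous input", {
  pr <- profile_and_restrict(rep("AVL", 8),
                             alphabets = list(`1` = c("A", "G"),
                                              `2` = c("V", "I"),
                                              `3` = c("L", "M")))
  expect_equal(pr$alphabets, list(`1` = "A", `2` = "V", `3` = "L"))
  # restriction is monotone
  pr2 <- profile_and_restrict(c("AVL", "GIL"), alphabets = pr$alphabets)
  expect_true(all(lengths(pr2$alphabets) <= lengths(pr$alphabets)))
  expect_error(profile_and_restrict(character(0)), "no sequences")
  expect_error(profile_and_restrict(c("AV", "AVL")), "length")
})

test_that("the enrichment loop matches exhaustive Boltzmann enumeration on a Potts toy", {
  m <- ovoid_model()[c(10, 60), ]
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  alpha <- list(`10` = c("A", "V", "L", "F"), `60` = c("A", "V", "L", "F"))
  h <- c(A = 0.3, V = 0.0, L = 0.8, F = 1.5)
  J <- function(a, b) ifelse(a == b, -0.7, 0)
  energy <- function(s) h[[s[1]]] + h[[s[2]]] + J(s[1], s[2])

  res <- iterate_enrichment(m, cls, energy, schedule = list("hydrophobic"),
                            n_traj = 300, seed = 3, max_rounds = 3,
                            steps_per_position = 60, alphabets = alpha)
  # exhaustive Boltzmann marginals over the 16 sequence pairs at T = 1
  combos <- expand.grid(a = alpha[[1]], b = alpha[[2]],
                        stringsAsFactors = FALSE)
  w <- exp(-apply(combos, 1, function(r) energy(c(r[1], r[2]))))
  w <- w / sum(w)
  marg1 <- tapply(w, combos$a, sum)
  marg2 <- tapply(w, combos$b, sum)
  prof <- res$profile$profile
  top1 <- prof$aa[prof$position == "10"][which.max(prof$freq[prof$position == "10"])]
  top2 <- prof$aa[prof$position == "60"][which.max(prof$freq[prof$position == "60"])]
  expect_equal(top1, names(which.max(marg1)))
  expect_equal(top2, names(which.max(marg2)))
  # frequencies track the Boltzmann marginals
  f1 <- stats::setNames(prof$freq[prof$position == "10"],
                        prof$aa[prof$position == "10"])
  expect_lt(max(abs(f1[names(marg1)] - marg1), na.rm = TRUE), 0.15)
})

test_that("alphabet sizes are non-increasing across enrichment rounds", {
  m <- ovoid_model()[1:6, ]
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  h <- c(A = 0, V = 1, I = 2, L = 3, M = 4, F = 5)
  energy <- function(s) sum(h[s])
  res <- iterate_enrichment(m, cls, energy, schedule = list("hydrophobic"),
                            n_traj = 40, seed = 7, max_rounds = 4,
                            steps_per_position = 30)
  expect_true(all(diff(res$log$mean_alphabet) <= 1e-9))
})

test_that("a dominant-residue energy collapses a single position quickly", {
  m <- ovoid_model()[5, , drop = FALSE]
  m <- ovoidtim:::as_barrel_model(m)
  cls <- tibble::tibble(residue = m$residue, class = "hydrophobic")
  energy <- function(s) ifelse(s[1] == "V", -8, 0)
  res <- iterate_enrichment(m, cls, energy, schedule = list("hydrophobic"),
                            n_traj = 60, seed = 2, max_rounds = 3,
                            steps_per_position = 40)
  expect_lte(max(res$log$round), 3)
  expect_equal(res$profile$alphabets[[as.character(m$residue)]], "V")
})

test_that("two-phase schedules hold the other classes fixed", {
  m <- ovoid_model()[1:8, ]
  cls <- tibble::tibble(residue = m$residue,
                        class = rep(c("hydrophobic", "solvent_exposed"), 4))
  energy <- function(s) 0
  seqs <- run_trajectories(m, cls, energy, n_traj = 20, seed = 1,
                           design_classes = "hydrophobic",
                           steps_per_position = 10)
  fixed_pos <- which(cls$class == "solvent_exposed")
  orig <- model_sequence(m)
  for (p in fixed_pos) {
    expect_true(all(substr(seqs$sequence, p, p) == orig[[p]]))
  }
  expect_error(run_trajectories(m, cls, energy, designable = integer(0)),
               "no designable")
})

test_that("the toy contact energy rewards hydrophobic cores", {
  m <- ovoid_model()
  en <- contact_energy(m)
  s_core <- m$aa
  s_polar <- m$aa
  core <- m$element == "strand" & m$facing == "core"
  s_polar[core] <- "K"
  expect_lt(en(s_core), en(s_polar))
})
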