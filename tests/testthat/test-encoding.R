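test_that("split-and-nick encoding produces the stated species", {
  # nothing nicked
  p0 <- encode_by_split(molecule_pool(), "A", 0)
  expect_equal(unname(p0$species), c(1, 0, 0, 0))
  # everything double nicked
  p1 <- encode_by_split(encode_by_split(molecule_pool(), "A", 1), "B", 1)
  expect_equal(unname(p1$species), c(0, 0, 0, 1))
  expect_equal(measure(p1, "both"), 1)
  # an arbitrary fraction lands in the singly nicked species
  p <- encode_by_split(molecule_pool(), "A", 3 / 8)
  expect_equal(measure(p, "nickA"), 0.375)
  # re-encoding an occupied site is refused
  expect_error(encode_by_split(p, "A", 0.2), "already carries nicks")
  expect_error(encode_by_split(molecule_pool(), "A", 1.2), "\\[0, 1\\]")
  expect_error(encode_by_split(molecule_pool(), "Q", 0.5), "unknown nick site")
})

test_that("ideal-mode double encoding multiplies exactly and conserves mass", {
  p <- encode_by_split(encode_by_split(molecule_pool(), "A", 0.9), "B", 0.8)
  expect_identical(measure(p, "both"), 0.9 * 0.8)
  expect_equal(sum(measure_all(p)$fraction), 1, tolerance = 1e-12)
  # product exactness over a coarse grid (the full grid runs in acceptance)
  for (a in seq(0, 1, by = 0.25)) {
    for (b in seq(0, 1, by = 0.25)) {
      q <- encode_by_split(encode_by_split(molecule_pool(), "A", a), "B", b)
      expect_identical(measure(q, "both"), a * b)
    }
  }
})

test_that("species_distribution matches the independent-nicking closed form", {
  expect_equal(
    unlist(species_distribution(1, 1)[, c("unnicked", "nickA", "nickB", "both")]),
    c(unnicked = 0, nickA = 0, nickB = 0, both = 1))
  d <- species_distribution(0.5, 0.5)
  expect_equal(unlist(d[, c("unnicked", "nickA", "nickB", "both")]),
               c(unnicked = 0.25, nickA = 0.25, nickB = 0.25, both = 0.25))
  # rows always sum to one
  g <- species_distribution(runif(50), runif(50))
  expect_equal(rowSums(g[, c("unnicked", "nickA", "nickB", "both")]),
               rep(1, 50), tolerance = 1e-12)
})

test_that("encoding order does not change the joint species distribution", {
  for (s in 1:5) {
    ab <- withr::with_seed(s, runif(2))
    p_ab <- encode_by_split(encode_by_split(molecule_pool(), "A", ab[1]), "B", ab[2])
    p_ba <- encode_by_split(encode_by_split(molecule_pool(), "B", ab[2]), "A", ab[1])
    expect_equal(p_ab$species, p_ba$species, tolerance = 1e-14)
  }
})

test_that("enzyme dosing follows E = b * t * (1/k) with overdose protection", {
  d <- dose_for_fraction(0.5, total = 1000, turnover = 10)
  expect_equal(d$count, 50)
  p <- molecule_pool(total = 1000, mode = "sampled")
  p <- nick_with_enzyme(p, enzyme_dose(50, "A", turnover = 10))
  expect_equal(measure(p, "nickA"), 0.5)
  # zero dose leaves the pool untouched
  q0 <- nick_with_enzyme(molecule_pool(), enzyme_dose(0, "A"))
  expect_equal(unname(q0$species), c(1, 0, 0, 0))
  # implied fraction above one is an overdose
  expect_error(nick_with_enzyme(molecule_pool(total = 100, mode = "sampled"),
                                enzyme_dose(60, "A", turnover = 2)),
               "overdose")
  expect_error(enzyme_dose(-1, "A"), "nonnegative")
  expect_error(nick_with_enzyme(molecule_pool(), enzyme_dose(0.5, "A"),
                                reaction_time_sufficient = FALSE),
               "reaction time")
})

test_that("sampled-mode nicking is Bernoulli per molecule with binomial moments", {
  t <- 1e5
  b <- 0.3
  fracs <- vapply(1:20, function(s) {
    p <- molecule_pool(total = t, mode = "sampled")
    p <- nick_with_enzyme(p, dose_for_fraction(b, t, target_site = "A"), seed = s)
    measure(p, "nickA")
  }, numeric(1))
  se <- sqrt(b * (1 - b) / t)
  expect_true(all(abs(fracs - b) < 4 * se))
  # mean over the 20 seeds is tighter still
  expect_lt(abs(mean(fracs) - b), 4 * se / sqrt(20))
})

test_that("sampled-mode species counts track the four-species closed form", {
  t <- 1e5
  a <- 0.6
  b <- 0.4
  p <- encode_by_split(molecule_pool(t, "sampled"), "A", a, seed = 11)
  p <- encode_by_split(p, "B", b, seed = 12)
  expected <- unlist(species_distribution(a, b)[, c("unnicked", "nickA", "nickB", "both")])
  for (s in names(expected)) {
    pr <- expected[[s]]
    se <- sqrt(pr * (1 - pr) / t)
    expect_lt(abs(p$species[[s]] / t - pr), 4 * se)
  }
  expect_equal(sum(p$species), t) # counts conserved exactly
})

test_that("deterministic count rounding preserves totals", {
  x <- c(2.5, 3.5, 0.4)
  r <- round_half_away(x)
  expect_equal(sum(r), round(sum(x)))
  expect_true(all(r == round(r)))
  # sampled-mode deterministic encode conserves the count
  p <- encode_by_split(molecule_pool(1001, "sampled"), "A", 1 / 3)
  expect_equal(sum(p$species), 1001)
})

test_that("pools survive a JSON round trip", {
  p <- encode_by_split(molecule_pool(1000, "sampled"), "A", 0.25, seed = 3)
  q <- pool_from_json(pool_to_json(p))
  expect_equal(q$species, p$species)
  expect_equal(q$mode, p$mode)
  expect_equal(q$seed_lineage, p$seed_lineage)
  expect_equal(q$template$pair_distance, p$template$pair_distance)
})
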