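test_that("linear fusion computes the weighted probability and its limits", {
  expect_equal(linear_fuse(0.9, 0.5, alpha = 0.7), 0.78)
  expect_equal(suppressWarnings(linear_fuse(0.3, 0.8, alpha = 1)), 0.3)
  expect_equal(linear_fuse(0.42, 0.42, alpha = 0.8), 0.42)  # agreement fixed point
  expect_warning(linear_fuse(0.5, 0.5, alpha = 0.3), "0.6, 0.9")
  expect_error(linear_fuse(1.2, 0.5, 0.7), "\\[0, 1\\]")
  expect_error(linear_fuse(0.5, -0.1, 0.7), "\\[0, 1\\]")
})

test_that("linear fusion is monotone in both inputs and in alpha when a > b", {
  set.seed(1)
  for (rep in 1:20) {
    a <- runif(1); b <- runif(1); al <- runif(1, 0.6, 0.9)
    eps <- 0.05
    f0 <- linear_fuse(a, b, al)
    expect_gte(linear_fuse(min(a + eps, 1), b, al), f0)
    expect_gte(linear_fuse(a, min(b + eps, 1), al), f0)
    if (a > b) {
      expect_gte(suppressWarnings(linear_fuse(a, b, min(al + eps, 1))), f0)
    }
  }
})

test_that("probability-to-mass conversion respects the discount split", {
  m1 <- mass_from_probability(1, discount = 0)
  expect_equal(unname(m1[["fall"]]), 1)
  m2 <- mass_from_probability(0.8, discount = 0.1)
  expect_equal(unname(m2), c(0.72, 0.18, 0.10))
  set.seed(3)
  for (rep in 1:20) {
    m <- mass_from_probability(runif(1), runif(1))
    expect_equal(sum(m), 1, tolerance = 1e-12)
  }
})

test_that("Dempster combination matches exhaustive product-term enumeration", {
  # worked pair: K = 0.44, renormalized singletons 0.48/0.56 and 0.08/0.56
  m1 <- mass_function(0.8, 0.2)
  m2 <- mass_function(0.6, 0.4)
  comb <- dempster_combine(m1, m2)
  expect_equal(attr(comb, "conflict"), 0.44)
  expect_equal(unname(comb[["fall"]]), 0.48 / 0.56, tolerance = 1e-12)
  expect_equal(unname(comb[["notfall"]]), 0.08 / 0.56, tolerance = 1e-12)
  # randomized agreement with the brute-force oracle
  set.seed(11)
  for (rep in 1:30) {
    r1 <- runif(3); r1 <- r1 / sum(r1)
    r2 <- runif(3); r2 <- r2 / sum(r2)
    ma <- mass_function(r1[1], r1[2], r1[3])
    mb <- mass_function(r2[1], r2[2], r2[3])
    got <- dempster_combine(ma, mb)
    want <- oracle_dempster(ma, mb)
    expect_equal(unname(got[1:3]), unname(want$mass), tolerance = 1e-12)
    expect_equal(attr(got, "conflict"), want$K, tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    # commutativity
    rev <- dempster_combine(mb, ma)
    expect_equal(unname(rev[1:3]), unname(got[1:3]), tolerance = 1e-12)
  }
})

test_that("vacuous evidence is neutral and certainty is preserved", {
  m <- mass_function(0.35, 0.45, 0.20)
  vac <- mass_function(0, 0, 1)
  expect_equal(unname(dempster_combine(m, vac)[1:3]), unname(m[1:3]),
               tolerance = 1e-12)
  sure <- mass_function(1, 0, 0)
  both <- dempster_combine(sure, sure)
  expect_equal(unname(both[["fall"]]), 1)
  expect_equal(attr(both, "conflict"), 0)
  expect_error(dempster_combine(mass_function(1, 0, 0), mass_function(0, 1, 0)),
               "total conflict")
})

test_that("with no discount Dempster fusion equals the Bayesian product rule", {
  set.seed(5)
  for (rep in 1:25) {
    a <- runif(1, 0.05, 0.95)
    b <- runif(1, 0.05, 0.95)
    comb <- dempster_combine(mass_from_probability(a), mass_from_probability(b))
    bayes <- a * b / (a * b + (1 - a) * (1 - b))
    expect_equal(unname(comb[["fall"]]), bayes, tolerance = 1e-12)
  }
})

test_that("belief and plausibility bound each hypothesis correctly", {
  vac <- mass_function(0, 0, 1)
  expect_equal(belief_plausibility(vac, "fall"), c(bel = 0, pl = 1))
  m <- mass_function(0.72, 0.18, 0.10)
  bp <- belief_plausibility(m, "fall")
  expect_equal(bp, c(bel = 0.72, pl = 0.82))
  expect_equal(belief_plausibility(m, "theta"), c(bel = 1, pl = 1))
  set.seed(9)
  for (rep in 1:20) {
    r <- runif(3); r <- r / sum(r)
    mm <- mass_function(r[1], r[2], r[3])
    f <- belief_plausibility(mm, "fall")
    n <- belief_plausibility(mm, "notfall")
    expect_lte(f[["bel"]], f[["pl"]])
    expect_equal(f[["pl"]], 1 - n[["bel"]], tolerance = 1e-12)
  }
})

test_that("decisions threshold scores and masses with a conservative tie rule", {
  expect_equal(decide(0.78), "fall")
  expect_equal(decide(0.5), "notfall")                     # tie -> notfall
  expect_equal(decide(mass_function(0, 1, 0)), "notfall")
  expect_equal(decide(mass_function(0.4, 0.2, 0.4)), "fall")  # pignistic 0.6
  expect_equal(decide(mass_function(0.4, 0.2, 0.4), rule = "belief"), "notfall")
})

test_that("score tables are fused by clip identity", {
  video <- data.frame(clip_id = c("a", "b", "c"), prob = c(0.9, 0.2, 0.6))
  audio <- data.frame(clip_id = c("c", "a", "b"), prob = c(0.4, 0.8, 0.1))
  lin <- fuse_scores(video, audio, "linear", alpha = 0.7)
  expect_equal(lin$fused[lin$clip_id == "a"], 0.7 * 0.9 + 0.3 * 0.8)
  expect_equal(lin$fused[lin$clip_id == "c"], 0.7 * 0.6 + 0.3 * 0.4)
  ds <- fuse_scores(video, audio, "dempster")
  expect_true(all(ds$conflict >= 0 & ds$conflict < 1))
  expect_error(fuse_scores(video, data.frame(clip_id = "z", prob = 0.5)),
               "overlap")
})
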