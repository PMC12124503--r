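test_that("sim_config validates its stated world", {
  expect_s3_class(sim_config(n_mothers = 10), "sim_config")
  expect_error(sim_config(sex_ratio_male = 1.2), "sex_ratio_male")
  # triples summing past 9 are rejected at construction
  bad <- data.frame(B = 5, G = 5, N = 0, prob = 1)
  expect_error(sim_config(ideal_dist = bad), "ideal family size > 9")
  expect_error(sim_config(births_dist = data.frame(k = 13, prob = 1)),
               "0..12")
  s <- diag(5); s[1, 2] <- s[2, 1] <- 1.5
  expect_error(sim_config(outcome_sigma = s), "outcome_sigma")
})

test_that("empty and degenerate populations", {
  cfg <- sim_config(n_mothers = 0, seed = 1)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$mothers), 0)
  expect_equal(nrow(pop$children), 0)
  expect_false(is.null(pop$truth$beta))
  # degenerate births at 0: mothers but no children
  cfg0 <- sim_config(n_mothers = 25,
                     births_dist = data.frame(k = 0, prob = 1), seed = 2)
  pop0 <- simulate_population(cfg0)
  expect_equal(nrow(pop0$mothers), 25)
  expect_equal(nrow(pop0$children), 0)
})

test_that("simulation is deterministic and CSVs byte-identical", {
  cfg <- sim_config(n_mothers = 150, seed = 9)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1$mothers, p2$mothers)
  expect_identical(p1$children, p2$children)
  d1 <- file.path(tempdir(), "popA"); d2 <- file.path(tempdir(), "popB")
  write_population(p1, d1); write_population(p2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "children.csv"))),
                   unname(tools::md5sum(file.path(d2, "children.csv"))))
})

test_that("population tables satisfy their structural invariants", {
  cfg <- sim_config(n_mothers = 400, seed = 4)
  pop <- simulate_population(cfg)
  ch <- pop$children
  expect_true(all(ch$mother_id %in% pop$mothers$mother_id))
  # contiguous birth orders within mother
  bo <- tapply(ch$birth_order, ch$mother_id,
               function(x) identical(sort(x), seq_along(x)))
  expect_true(all(unlist(bo)))
  for (oc in c(colnames(cfg$outcome_beta), names(cfg$treat_probs)))
    expect_true(all(ch[[oc]] %in% c(0L, 1L)), info = oc)
})

test_that("preference draws follow a stated two-point distribution", {
  two <- data.frame(B = c(2, 1), G = c(1, 0), N = c(0, 1),
                    prob = c(0.3, 0.7))
  cfg <- sim_config(ideal_dist = two, seed = 5)
  set.seed(5)
  pr <- generate_preferences(cfg, 10000)
  phat <- mean(pr$B_m == 2)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(phat - 0.3), 3 * se)
  # degenerate distribution is constant
  one <- data.frame(B = 2, G = 1, N = 1, prob = 1)
  cfg1 <- sim_config(ideal_dist = one, seed = 6)
  pr1 <- generate_preferences(cfg1, 50)
  expect_true(all(pr1$C_m == 4))
})

test_that("birth histories respect sex ratio and death settings", {
  cfg <- sim_config(births_dist = data.frame(k = 6, prob = 1),
                    u5_death_prob = 0, seed = 7)
  set.seed(7)
  h <- generate_birth_history(fertility_pref(1, 1, 0), cfg)
  expect_equal(nrow(h), 6)
  expect_true(all(h$alive == 1))
  # 3-SE binomial check on the male fraction
  cfg2 <- sim_config(n_mothers = 10000, sex_ratio_male = 0.512,
                     births_dist = data.frame(k = 5, prob = 1), seed = 8)
  pop <- simulate_population(cfg2)
  phat <- mean(pop$children$sex == "M")
  se <- sqrt(0.512 * 0.488 / nrow(pop$children))
  expect_lt(abs(phat - 0.512), 3 * se)
})

test_that("latent-Gaussian outcomes match closed-form orthants", {
  set.seed(11)
  # beta = 0, J = 1: P(y = 1) = 0.5
  y <- generate_outcomes(matrix(1, 20000, 1), matrix(0, 1, 1),
                         matrix(1, 1, 1))
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 20000))
  # beta = 0, rho = 0.5: P(1,1) = 1/4 + asin(rho)/(2 pi) = 1/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  y2 <- generate_outcomes(matrix(1, 30000, 1), matrix(0, 1, 2), S)
  p11 <- mean(y2[, 1] == 1 & y2[, 2] == 1)
  expect_lt(abs(p11 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 30000))
  # huge intercept: almost surely 1
  y3 <- generate_outcomes(matrix(1, 100, 1), matrix(10, 1, 1),
                          matrix(1, 1, 1))
  expect_true(all(y3 == 1))
  expect_error(generate_outcomes(matrix(1, 5, 2), matrix(0, 1, 1),
                                 matrix(1, 1, 1)), "design")
})

test_that("covariate marginals are calibrated", {
  cfg <- sim_config(n_mothers = 12000, seed = 12)
  pop <- simulate_population(cfg)
  sp <- cfg$covariate_spec$wealth
  for (i in seq_along(sp$levels)) {
    phat <- mean(pop$mothers$wealth == sp$levels[i])
    se <- sqrt(sp$probs[i] * (1 - sp$probs[i]) / 12000)
    expect_lt(abs(phat - sp$probs[i]), 3 * se)
  }
})

test_that("analytic prevalence: trivial cases", {
  cfg0 <- sim_config(births_dist = data.frame(k = 0, prob = 1))
  ap0 <- analytic_excess_prevalence(cfg0)
  expect_equal(ap0$child$percent, rep(0, 4))
  expect_equal(ap0$mother$percent, rep(0, 4))
  # zero ideal, one certain birth, no deaths: parity prevalence 100%
  cfg1 <- sim_config(ideal_dist = data.frame(B = 0, G = 0, N = 0, prob = 1),
                     births_dist = data.frame(k = 1, prob = 1),
                     u5_death_prob = 0)
  ap1 <- analytic_excess_prevalence(cfg1)
  expect_equal(ap1$child$percent[ap1$child$category == "excess_parity"], 100)
  expect_equal(ap1$mother$percent[ap1$mother$category == "excess_parity"],
               100)
})

test_that("analytic prevalence matches Monte Carlo on a mixed config", {
  cfg <- sim_config(n_mothers = 30000, seed = 21)
  pop <- simulate_population(cfg)
  fl <- classify_population(pop$mothers, pop$children)
  agg <- aggregate_excess(fl, n_mothers = nrow(pop$mothers))
  ap <- analytic_excess_prevalence(cfg)
  for (i in 1:4) {
    p <- ap$child$percent[i] / 100
    # cluster-robust-ish bound: binomial SE inflated for within-mother
    # correlation (children of one mother share flags)
    se <- 2 * sqrt(p * (1 - p) / nrow(pop$children)) * 100
    expect_lt(abs(agg$child$percent[i] - ap$child$percent[i]),
              max(3 * se, 0.5), label = ap$child$category[i])
    pm <- ap$mother$percent[i] / 100
    sem <- sqrt(pm * (1 - pm) / nrow(pop$mothers)) * 100
    expect_lt(abs(agg$mother$percent[i] - ap$mother$percent[i]), 3 * sem)
  }
})

test_that("tetrachoric structure of generated outcomes recovers sigma", {
  # beta = 0 so the latent correlation is the only structure
  beta0 <- matrix(0, length(sim_design_cols), 2,
                  dimnames = list(sim_design_cols, c("a", "b")))
  S <- matrix(c(1, 0.45, 0.45, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  cfg <- sim_config(n_mothers = 12000, outcome_beta = beta0,
                    outcome_sigma = S, seed = 31)
  pop <- simulate_population(cfg)
  r <- tetrachoric_pair(table(pop$children$a, pop$children$b))
  expect_lt(abs(as.numeric(r) - 0.45), 0.05)
})
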