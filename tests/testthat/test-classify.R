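test_that("fertility_pref validates and derives the ideal family size", {
  p <- fertility_pref(2, 1, 1)
  expect_equal(p$C, 4L)
  expect_error(fertility_pref(5, 3, 2), "exceeds the eligibility cap")
  expect_error(fertility_pref(-1, 0, 0), "non-negative")
})

test_that("six-child worked history reproduces the published statuses", {
  flags <- classify_children_sequential(
    fertility_pref(2, 1, 1), c("B", "B", "B", "B", "D1", "G", "B"))
  expect_equal(flags$excess_gender, c(0L, 0L, 0L, 1L, 0L, 1L))
  expect_equal(flags$excess_parity, c(0L, 0L, 0L, 0L, 0L, 1L))
  expect_equal(flags$excess_dual,   c(0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("sequential classifier edge rules", {
  # zero ideal: every child is parity- and sex-excess
  fl <- classify_children_sequential(fertility_pref(0, 0, 0), c("G"))
  expect_equal(fl$excess_parity, 1L)
  expect_equal(fl$excess_girls, 1L)
  # large quota: no flags
  fl <- classify_children_sequential(fertility_pref(9, 0, 0), c("B"))
  expect_equal(sum(fl$excess_gender) + sum(fl$excess_parity), 0L)
  # death of unknown child errors
  expect_error(
    classify_children_sequential(fertility_pref(1, 1, 0), c("B", "D5")),
    "unknown child")
  expect_error(
    classify_children_sequential(fertility_pref(1, 1, 0),
                                 c("B", "D1", "D1")),
    "already-dead")
})

test_that("sequential classifier agrees with the slot-consumption oracle", {
  prefs <- all_pref_triples(4)
  seqs <- all_birth_sequences(4)  # exhaustive small core
  for (i in seq_len(nrow(prefs))) {
    pref <- fertility_pref(prefs$B[i], prefs$G[i], prefs$N[i])
    for (ev in seqs) {
      got <- classify_children_sequential(pref, ev)
      want <- oracle_classify(pref, ev)
      expect_equal(got$excess_gender, want$excess_gender,
                   info = sprintf("pref (%d,%d,%d) events %s",
                                  pref$B, pref$G, pref$N,
                                  paste(ev, collapse = "")))
      expect_equal(got$excess_parity, want$excess_parity)
    }
  }
})

test_that("with no deaths, parity-flagged children number max(0, C_i - C_m)", {
  set.seed(71)
  for (rep in 1:50) {
    pref <- fertility_pref(sample(0:3, 1), sample(0:3, 1), sample(0:2, 1))
    k <- sample(1:6, 1)
    ev <- sample(c("B", "G"), k, replace = TRUE)
    fl <- classify_children_sequential(pref, ev)
    expect_equal(sum(fl$excess_parity), max(0L, k - pref$C))
  }
})

test_that("appending a birth never revises earlier flags (no deaths)", {
  set.seed(72)
  for (rep in 1:25) {
    pref <- fertility_pref(sample(0:3, 1), sample(0:2, 1), sample(0:2, 1))
    ev <- sample(c("B", "G"), 6, replace = TRUE)
    full <- classify_children_sequential(pref, ev)
    part <- classify_children_sequential(pref, ev[1:4])
    expect_equal(full$excess_gender[1:4], part$excess_gender)
    expect_equal(full$excess_parity[1:4], part$excess_parity)
  }
})

test_that("static mother classifier matches the three inequalities", {
  # worked-example end state: 3 living boys + 1 girl, ideal (2,1,1)
  fl <- classify_mother_static(fertility_pref(2, 1, 1),
                               sex = c("M", "M", "M", "M", "F"),
                               alive = c(1, 1, 0, 1, 1))
  expect_equal(unname(fl), c(0L, 0L, 0L, 0L))
  # brute force over a small grid
  prefs <- all_pref_triples(4)
  set.seed(73)
  for (rep in 1:100) {
    i <- sample.int(nrow(prefs), 1)
    pref <- fertility_pref(prefs$B[i], prefs$G[i], prefs$N[i])
    k <- sample(0:5, 1)
    sex <- if (k > 0) sample(c("M", "F"), k, replace = TRUE) else character(0)
    alive <- if (k > 0) sample(0:1, k, replace = TRUE) else integer(0)
    got <- classify_mother_static(pref, sex, alive)
    Bi <- sum(sex == "M" & alive == 1); Gi <- sum(sex == "F" & alive == 1)
    Ci <- sum(alive)
    expect_equal(got[["excess_parity"]], as.integer(Ci - pref$C > 0))
    expect_equal(got[["excess_boys"]], as.integer(Bi - (pref$B + pref$N) > 0))
    expect_equal(got[["excess_girls"]], as.integer(Gi - (pref$G + pref$N) > 0))
  }
})

test_that("dual rules differ as documented", {
  # one living boy and one living girl over a zero ideal: both sexes in
  # excess but parity too, so both rules flag the mother
  both <- classify_mother_static(fertility_pref(0, 0, 0), c("M", "F"),
                                 dual_rule = "both_sexes")
  sap <- classify_mother_static(fertility_pref(0, 0, 0), c("M", "F"),
                                dual_rule = "sex_and_parity")
  expect_equal(both[["excess_dual"]], 1L)
  expect_equal(sap[["excess_dual"]], 1L)
  # an excess boy without parity excess: sex_and_parity says no dual
  p <- fertility_pref(0, 2, 0)
  sap2 <- classify_mother_static(p, c("M"), dual_rule = "sex_and_parity")
  both2 <- classify_mother_static(p, c("M"), dual_rule = "both_sexes")
  expect_equal(sap2[["excess_dual"]], 0L)
  expect_equal(both2[["excess_dual"]], 0L)
})

test_that("vectorised population classifier equals the event-loop path", {
  set.seed(74)
  prefs <- all_pref_triples(4)
  mothers <- list(); children <- list()
  for (m in 1:60) {
    i <- sample.int(nrow(prefs), 1)
    k <- sample(0:6, 1)
    mothers[[m]] <- data.frame(mother_id = m, B_m = prefs$B[i],
                               G_m = prefs$G[i], N_m = prefs$N[i])
    if (k > 0)
      children[[m]] <- data.frame(
        mother_id = m, birth_order = 1:k,
        sex = sample(c("M", "F"), k, replace = TRUE),
        alive = sample(0:1, k, replace = TRUE, prob = c(0.15, 0.85)))
  }
  mo <- do.call(rbind, mothers); ch <- do.call(rbind, children)
  vec <- classify_population(mo, ch)
  for (m in unique(ch$mother_id)) {
    sub <- ch[ch$mother_id == m, ]
    pref <- fertility_pref(mo$B_m[m], mo$G_m[m], mo$N_m[m])
    # immediate-death event order: birth then (death) per child
    ev <- character(0)
    for (i in seq_len(nrow(sub))) {
      ev <- c(ev, ifelse(sub$sex[i] == "M", "B", "G"))
      if (sub$alive[i] == 0) ev <- c(ev, paste0("D", i))
    }
    loop <- classify_children_sequential(pref, ev)
    vsub <- vec[vec$mother_id == m, ]
    expect_equal(vsub$excess_gender, loop$excess_gender)
    expect_equal(vsub$excess_parity, loop$excess_parity)
    expect_equal(vsub$excess_dual, loop$excess_dual)
  }
})

test_that("static/sequential consistency without deaths", {
  set.seed(75)
  prefs <- all_pref_triples(4)
  for (rep in 1:80) {
    i <- sample.int(nrow(prefs), 1)
    pref <- fertility_pref(prefs$B[i], prefs$G[i], prefs$N[i])
    k <- sample(1:6, 1)
    ev <- sample(c("B", "G"), k, replace = TRUE)
    seqfl <- classify_children_sequential(pref, ev)
    stat <- classify_mother_static(pref, chartr("BG", "MF", ev))
    expect_equal(any(seqfl$excess_parity == 1L),
                 stat[["excess_parity"]] == 1L)
    # total gender-flagged children = births minus occupied slots
    # (either-gender slots absorb min(N, total overflow), whatever the
    # birth order)
    n_boys <- sum(ev == "B"); n_girls <- sum(ev == "G")
    used <- min(n_boys, pref$B) + min(n_girls, pref$G) +
      min(pref$N, max(0L, n_boys - pref$B) + max(0L, n_girls - pref$G))
    expect_equal(sum(seqfl$excess_gender), n_boys + n_girls - used)
  }
})

test_that("aggregate_excess counts children and mothers", {
  toy <- toy_population()
  fl <- classify_population(toy$mothers, toy$children)
  agg <- aggregate_excess(fl, n_mothers = 3)
  expect_equal(agg$child$n_total, rep(8, 4))
  expect_true(all(agg$child$percent >= 0 & agg$child$percent <= 100))
  expect_true(all(agg$mother$percent >= 0 & agg$mother$percent <= 100))
  # mother 2 (zero ideal) has its only child parity-flagged
  expect_equal(fl[fl$mother_id == 2, ]$excess_parity, 1L)
  # no flags -> zero prevalence
  none <- data.frame(mother_id = 1, excess_boys = 0, excess_girls = 0,
                     excess_parity = 0, excess_dual = 0)
  agg0 <- aggregate_excess(none)
  expect_equal(agg0$child$percent, rep(0, 4))
})

test_that("flags are invariant to mother relabeling", {
  toy <- toy_population()
  fl1 <- classify_population(toy$mothers, toy$children)
  mo2 <- toy$mothers; mo2$mother_id <- mo2$mother_id + 10
  ch2 <- toy$children; ch2$mother_id <- ch2$mother_id + 10
  fl2 <- classify_population(mo2, ch2)
  expect_equal(fl1$excess_gender, fl2$excess_gender)
  expect_equal(fl1$excess_parity, fl2$excess_parity)
})

test_that("eligibility filters drop and report correctly", {
  mo <- data.frame(mother_id = 1:5,
                   B_m = c(2, 5, 1, NA, 3), G_m = c(2, 5, 1, 1, 3),
                   N_m = c(0, 2, 0, 0, 4))
  ch <- data.frame(mother_id = c(1, 2, 3, 4, 5),
                   birth_order = 1, sex = "M", alive = 1)
  out <- apply_eligibility_filters(mo, ch)
  rep_ <- out$report
  expect_equal(rep_$n[rep_$rule == "ideal>9"], 2)       # 12 and 10
  expect_equal(rep_$n[rep_$rule == "ideal_missing"], 1)
  expect_equal(nrow(out$mothers), 2)
  expect_equal(nrow(out$children), 2)
  # totals reconcile: 5 = retained + dropped
  expect_equal(5, rep_$n[rep_$rule == "mothers_retained"] +
                 rep_$n[rep_$rule == "ideal>9"] +
                 rep_$n[rep_$rule == "ideal_missing"])
  # no-op when all eligible
  out2 <- apply_eligibility_filters(out$mothers, out$children)
  expect_equal(nrow(out2$mothers), 2)
  expect_error(apply_eligibility_filters(mo[, -2], ch), "B_m")
})
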