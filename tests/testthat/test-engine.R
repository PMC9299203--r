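mk_metrics <- function(n_fields, n_locations, aoo, eoo) {
  structure(list(n_fields = n_fields, n_locations = n_locations,
                 aoo_km2 = aoo, eoo_km2 = eoo), class = "range_metrics")
}
mk_threat <- function(regimes_vec) {
  n <- length(regimes_vec)
  locs <- data.frame(location_id = sprintf("L%02d", seq_len(n)),
                     site_id = sprintf("s%02d", seq_len(n)),
                     management_area_id = sprintf("A%d", seq_len(n)),
                     stringsAsFactors = FALSE)
  derive_threat_summary(locs, regime_table(sprintf("A%d", seq_len(n)),
                                           regimes_vec))
}

test_that("criterion B fires at the highest tier whose conditions all hold", {
  th <- threshold_table()
  # single tiny field under license: CR on both B1 and B2
  b <- evaluate_criterion_b(mk_metrics(1, 1, 4, 4),
                            mk_threat("EXPLORATION_LICENSE"), th)
  expect_equal(b$b1$tier, "CR")
  expect_equal(b$b2$tier, "CR")
  # EOO 171.23 and AOO 12 exceed the CR bounds of 100 and 10: EN, not CR
  b <- evaluate_criterion_b(mk_metrics(3, 1, 12, 171.23),
                            mk_threat("EXPLORATION_LICENSE"), th)
  expect_equal(b$b1$tier, "EN")
  expect_equal(b$b2$tier, "EN")
  expect_true(any(grepl("^a:", b$b1$satisfied_conditions)))
  expect_true(any(grepl("b\\(iii\\)", b$b1$satisfied_conditions)))
  # without continuing decline only condition a holds, which cannot suffice
  b <- evaluate_criterion_b(mk_metrics(3, 1, 12, 171.23),
                            mk_threat("UNPROTECTED_NO_LICENSE"), th)
  expect_equal(b$b1$tier, "none")
  expect_equal(b$b2$tier, "none")
  expect_length(b$b1$satisfied_conditions, 0)
})

test_that("criterion D2 requires restriction, plausible threat and a CR worst case", {
  th <- threshold_table()
  d <- evaluate_criterion_d2(mk_metrics(4, 4, 16, 400),
                             mk_threat(rep("UNPROTECTED_NO_LICENSE", 4)),
                             th, worst_case = "CR")
  expect_equal(d$tier, "VU")
  # effective protection removes the plausible threat
  d <- evaluate_criterion_d2(mk_metrics(2, 2, 8, 100),
                             mk_threat(rep("PROTECTED_EFFECTIVE", 2)),
                             th, worst_case = "EN")
  expect_equal(d$tier, "none")
  # a plausible threat whose realisation stops at EN does not fire D2
  d <- evaluate_criterion_d2(mk_metrics(2, 2, 8, 100),
                             mk_threat(rep("UNPROTECTED_NO_LICENSE", 2)),
                             th, worst_case = "EN")
  expect_equal(d$tier, "none")
})

test_that("categories, possibly-extinct tag and criteria strings assemble correctly", {
  th <- threshold_table()
  # CR with the whole range under active extraction: possibly extinct
  threat <- mk_threat("ACTIVE_MINING")
  m <- mk_metrics(1, 1, 4, 4)
  b <- evaluate_criterion_b(m, threat, th)
  d2 <- evaluate_criterion_d2(m, threat, th, "CR")
  a <- assign_category(b$b1, b$b2, d2, threat, "CR", m)
  expect_equal(a$category, "CR")
  expect_true(a$possibly_extinct)
  expect_equal(a$criteria_string, "B1ab(iii)+2ab(iii)")
  # fully protected: LC with empty criteria string
  threat <- mk_threat(rep("PROTECTED_EFFECTIVE", 2))
  m <- mk_metrics(2, 2, 8, 100)
  b <- evaluate_criterion_b(m, threat, th)
  d2 <- evaluate_criterion_d2(m, threat, th, "EN")
  a <- assign_category(b$b1, b$b2, d2, threat, "EN", m)
  expect_equal(a$category, "LC")
  expect_false(a$possibly_extinct)
  expect_equal(a$criteria_string, "")
  # mixed protected/unprotected with no tier fired: NT
  threat <- mk_threat(c("PROTECTED_EFFECTIVE", "UNPROTECTED_NO_LICENSE"))
  b <- evaluate_criterion_b(m, threat, th)
  d2 <- evaluate_criterion_d2(m, threat, th, "EN")
  a <- assign_category(b$b1, b$b2, d2, threat, "EN", m)
  expect_equal(a$category, "NT")
  # D2-only VU reports "D2"
  threat <- mk_threat(rep("UNPROTECTED_NO_LICENSE", 3))
  m <- mk_metrics(3, 3, 12, 30000)
  b <- evaluate_criterion_b(m, threat, th)
  d2 <- evaluate_criterion_d2(m, threat, th, "CR")
  a <- assign_category(b$b1, b$b2, d2, threat, "CR", m)
  expect_equal(a$criteria_string, "D2")
  expect_equal(a$category, "VU")
})

test_that("single-criterion strings keep the B1/B2 distinction", {
  th <- threshold_table()
  threat <- mk_threat(rep("EXPLORATION_LICENSE", 4))
  # B2 fires at EN (AOO small) while B1 stays at VU (EOO large): string B2 only
  m <- mk_metrics(4, 4, 16, 8000)
  b <- evaluate_criterion_b(m, threat, th)
  d2 <- evaluate_criterion_d2(m, threat, th, "EN")
  a <- assign_category(b$b1, b$b2, d2, threat, "EN", m)
  expect_equal(a$category, "EN")
  expect_equal(a$criteria_string, "B2ab(iii)")
})

test_that("engine agrees with a brute-force decision table on the full grid", {
  patterns <- list(
    protected = function(n) rep("PROTECTED_EFFECTIVE", n),
    unprotected = function(n) rep("UNPROTECTED_NO_LICENSE", n),
    licensed = function(n) rep("EXPLORATION_LICENSE", n),
    active = function(n) rep("ACTIVE_MINING", n),
    mixed = function(n) c(rep("EXPLORATION_LICENSE", ceiling(n / 2)),
                          rep("PROTECTED_EFFECTIVE", n - ceiling(n / 2))))
  eoos <- c(50, 171.23, 4000, 15000, 50000)
  aoos <- c(4, 16, 24, 400, 1200, 2400)
  for (nloc in 1:12) {
    for (p in names(patterns)) {
      regs <- patterns[[p]](nloc)
      for (eoo in eoos) {
        for (aoo in aoos) {
          eoo_use <- max(eoo, aoo)
          got <- engine_category(eoo_use, aoo, nloc, regs)
          want <- oracle_category(eoo_use, aoo, nloc, regs)
          expect_equal(got$category, want$category,
                       info = sprintf("nloc=%d %s eoo=%g aoo=%g",
                                      nloc, p, eoo_use, aoo))
          expect_equal(got$possibly_extinct, want$possibly_extinct,
                       info = sprintf("nloc=%d %s eoo=%g aoo=%g",
                                      nloc, p, eoo_use, aoo))
        }
      }
    }
  }
})

test_that("category is monotone under regime escalation and range shrinkage", {
  rank_cat <- function(a) match(a$category, CATEGORIES) +
    0.5 * a$possibly_extinct
  set.seed(13)
  for (trial in 1:100) {
    nloc <- sample(1:12, 1)
    regs <- sample(REGIMES, nloc, replace = TRUE)
    aoo <- 4 * sample(c(1, 4, 6, 100, 550), 1)
    eoo <- max(aoo, sample(c(50, 400, 8000, 30000), 1))
    base <- engine_category(eoo, aoo, nloc, regs)
    # escalate a random location's regime
    i <- sample.int(nloc, 1)
    sev <- match(regs[i], REGIMES)
    if (sev < 4) {
      regs2 <- regs
      regs2[i] <- REGIMES[sev + 1]
      expect_gte(rank_cat(engine_category(eoo, aoo, nloc, regs2)),
                 rank_cat(base))
    }
    # with decline present, shrinking the range never lowers the category
    if (any(regs %in% c("EXPLORATION_LICENSE", "ACTIVE_MINING"))) {
      shrunk <- engine_category(max(eoo / 10, aoo / 2), aoo / 2,
                                max(1, nloc - 1),
                                regs[seq_len(max(1, nloc - 1))])
      # shrinking can only matter if decline persists in the kept locations
      kept <- regs[seq_len(max(1, nloc - 1))]
      if (any(kept %in% c("EXPLORATION_LICENSE", "ACTIVE_MINING"))) {
        expect_gte(match(shrunk$category, CATEGORIES),
                   match(base$category, CATEGORIES) -
                     (base$possibly_extinct && !shrunk$possibly_extinct))
      }
    }
  }
})

test_that("a licensed location precludes LC; full protection guarantees LC", {
  set.seed(21)
  for (trial in 1:100) {
    nloc <- sample(1:12, 1)
    regs <- sample(REGIMES, nloc, replace = TRUE)
    aoo <- 4 * sample(1:20, 1)
    eoo <- max(aoo, sample(c(100, 5000, 40000), 1))
    a <- engine_category(eoo, aoo, nloc, regs)
    if (any(regs %in% c("EXPLORATION_LICENSE", "ACTIVE_MINING"))) {
      expect_true(a$category != "LC")
    }
    if (all(regs == "PROTECTED_EFFECTIVE")) {
      expect_equal(a$category, "LC")
    }
  }
})

test_that("an empty occurrence set is data deficient", {
  a <- assess_species(NULL, regime_table("A1", "ACTIVE_MINING"))
  expect_equal(a$category, "DD")
  expect_equal(a$criteria_string, "")
})
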