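cognition_grid <- function() {
  expand.grid(comatose = 0:1, short_term_memory_problem = 0:1,
              decision_making = 0:3, making_self_understood = 0:3,
              adl_eating = c(0:6, 8), KEEP.OUT.ATTRS = FALSE)
}

test_that("CPS matches the transcribed scoring grid on every input", {
  g <- cognition_grid()
  got <- cps_score(g)
  want <- mapply(cps_oracle_one, g$comatose, g$short_term_memory_problem,
                 g$decision_making, g$making_self_understood, g$adl_eating)
  expect_identical(got, as.integer(want))
  expect_true(all(got >= 0 & got <= 6))
})

test_that("CPS anchor cases behave as published", {
  a <- intact_assessment_items()
  expect_identical(cps_score(a), 0L)

  a$comatose <- 1L
  expect_identical(cps_score(a), 6L)

  b <- intact_assessment_items()
  b$decision_making <- 3L
  b$adl_eating <- 6L
  expect_identical(cps_score(b), 6L)
  b$adl_eating <- 0L
  expect_identical(cps_score(b), 5L)
})

test_that("CPS is non-computable (NA) when a required item is missing", {
  a <- intact_assessment_items()
  a$decision_making <- NA_integer_
  expect_true(is.na(cps_score(a)))
  b <- intact_assessment_items()
  b$adl_eating <- NA_integer_
  expect_true(is.na(cps_score(b)))
})

adl_grid <- function(codes = c(0:6, 8)) {
  expand.grid(adl_hygiene = codes, adl_toilet_use = codes,
              adl_locomotion = codes, adl_eating = codes,
              KEEP.OUT.ATTRS = FALSE)
}

test_that("ADL hierarchy matches the transcribed grid on all 8^4 inputs", {
  g <- adl_grid()
  got <- adl_hierarchy(g)
  want <- mapply(adlh_oracle_one, g$adl_hygiene, g$adl_toilet_use,
                 g$adl_locomotion, g$adl_eating)
  expect_identical(got, as.integer(want))
  expect_true(all(got >= 0 & got <= 6))
  expect_identical(adl_hierarchy(data.frame(adl_hygiene = 0, adl_toilet_use = 0,
                                            adl_locomotion = 0, adl_eating = 0)),
                   0L)
  expect_identical(adl_hierarchy(data.frame(adl_hygiene = 6, adl_toilet_use = 6,
                                            adl_locomotion = 6, adl_eating = 6)),
                   6L)
})

test_that("raising any single ADL item never lowers the hierarchy score", {
  g <- adl_grid(0:6)
  base <- adl_hierarchy(g)
  for (cc in c("adl_hygiene", "adl_toilet_use", "adl_locomotion",
               "adl_eating")) {
    can_raise <- g[[cc]] < 6
    g2 <- g[can_raise, , drop = FALSE]
    g2[[cc]] <- g2[[cc]] + 1L
    expect_true(all(adl_hierarchy(g2) >= base[can_raise]),
                info = paste("monotone in", cc))
  }
})

test_that("ADL decline fires only on strict worsening", {
  a <- intact_assessment_items()
  expect_false(adl_decline(a, a))
  worse <- a
  worse$adl_hygiene <- 4L  # hierarchy 3
  expect_true(adl_decline(a, worse))
  expect_false(adl_decline(worse, a))  # improvement is not decline
  missing <- a
  missing$adl_eating <- NA_integer_
  expect_true(is.na(adl_decline(missing, worse)))
})

test_that("behaviour disturbance is the OR of its four flags", {
  a <- intact_assessment_items()
  expect_false(behavior_disturbance(a))
  for (cc in c("verbally_abusive", "physically_abusive",
               "socially_inappropriate", "resists_care")) {
    b <- a
    b[[cc]] <- 1L
    expect_true(behavior_disturbance(b), info = cc)
  }
  all4 <- a
  all4[c("verbally_abusive", "physically_abusive",
         "socially_inappropriate", "resists_care")] <- 1L
  expect_true(behavior_disturbance(all4))
})

test_that("institutional risk counts exactly 8 categories, active iff >= 3", {
  flags_grid <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  for (i in seq_len(nrow(flags_grid))) {
    flags <- unlist(flags_grid[i, ])
    a <- risk_category_items(flags)
    r <- institutional_risk(a, adl_declined = flags[5])
    expect_equal(r$count, sum(flags))
    expect_equal(r$active, sum(flags) >= 3)
  }
})

test_that("risk category edge anchors: none, exactly three, all eight", {
  r0 <- institutional_risk(intact_assessment_items())
  expect_equal(r0$count, 0L)
  expect_false(r0$active)

  r3 <- institutional_risk(risk_category_items(
    c(TRUE, TRUE, TRUE, rep(FALSE, 5))))
  expect_true(r3$active)

  r8 <- institutional_risk(risk_category_items(rep(TRUE, 8)),
                           adl_declined = TRUE)
  expect_equal(r8$count, 8L)
  expect_true(r8$active)
})

test_that("the home-care activation cut-off (4) is available by config", {
  a <- risk_category_items(c(TRUE, TRUE, TRUE, rep(FALSE, 5)))
  expect_true(institutional_risk(a)$active)
  expect_false(institutional_risk(a, cutoff = 4L)$active)
})

test_that("going-out polarity is homebound-by-default and overridable", {
  a <- intact_assessment_items()  # goes out
  expect_equal(institutional_risk(a)$count, 0L)
  a$goes_out <- 0L
  expect_equal(institutional_risk(a)$count, 1L)
  expect_equal(institutional_risk(a, homebound_is_risk = FALSE)$count, 0L)
})

test_that("geriatric screener is monotone over its boolean inputs and ignores stamina", {
  g <- expand.grid(short_term_memory_problem = 0:1, decision_making = 0:1,
                   medication_management_problem = 0:1,
                   meal_preparation_problem = 0:1, KEEP.OUT.ATTRS = FALSE)
  base <- intact_assessment_items()
  scores <- vapply(seq_len(nrow(g)), function(i) {
    a <- base
    a[names(g)] <- g[i, ]
    cps_unused <- geriatric_screener(a)
    cps_unused
  }, integer(1))
  expect_equal(scores, rowSums(g), ignore_attr = TRUE)
  # switching any flag on never lowers the score (exhaustive by construction)
  for (cc in names(g)) {
    off <- g[[cc]] == 0
    g_on <- g[off, ]; g_on[[cc]] <- 1
    expect_true(all(rowSums(g_on) >= rowSums(g[off, ])))
  }
  # a stamina-like column has no effect
  with_stamina <- base
  with_stamina$stamina_problem <- 1L
  expect_identical(geriatric_screener(with_stamina),
                   geriatric_screener(base))
})

test_that("scale operations are pure and warn when boolean flags are missing", {
  a <- intact_assessment_items()
  a$decision_making <- 2L
  expect_identical(cps_score(a), cps_score(a))
  b <- intact_assessment_items()
  b$resists_care <- NA_integer_
  expect_warning(res <- behavior_disturbance(b), "not present")
  expect_false(res)
})

test_that("the did-not-occur ADL code maps to total dependence, configurably", {
  a <- intact_assessment_items()
  a$adl_eating <- 8L
  expect_identical(adl_hierarchy(a), 5L)       # eating treated as total
  expect_identical(adl_hierarchy(a, did_not_occur = 0L), 0L)
})
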