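test_that("health classification follows the three-question rule", {
  expect_equal(classify_health("no", "no", "no"), "healthy")
  expect_equal(classify_health("no", "yes", NA), "not_healthy")
  expect_equal(classify_health(NA, NA, NA), "missing")
  # a partial response with no "yes" is healthy: the record is missing only
  # when no limitation question was answered at all
  expect_equal(classify_health("no", NA, NA), "healthy")
  expect_equal(classify_health("no", "no", NA), "healthy")
  expect_error(classify_health("maybe", "no", "no"), "yes/no")
})

test_that("work classification keys on the working-now answer", {
  expect_equal(classify_work("working now"), "working")
  expect_equal(classify_work("retired"), "not_working")
  expect_equal(classify_work("temporarily laid off"), "not_working")
  expect_equal(classify_work("disabled and unable to work"), "not_working")
  expect_equal(classify_work(NA), "missing")
  expect_error(classify_work("sabbatical"), "allowed")
})

test_that("state encoding covers the 2x2 grid plus missingness codes", {
  expect_equal(encode_state("healthy", "working", "alive"), 1L)
  expect_equal(encode_state("healthy", "not_working", "alive"), 2L)
  expect_equal(encode_state("not_healthy", "working", "alive"), 3L)
  expect_equal(encode_state("not_healthy", "not_working", "alive"), 4L)
  expect_equal(encode_state("missing", "working", "alive"), -1L)
  expect_equal(encode_state("healthy", "missing", "alive"), -1L)
  expect_equal(encode_state("healthy", "working", "dead"), 5L)
  expect_equal(encode_state("missing", "missing", "unknown"), -2L)
  # total on the whole answer lattice
  for (h in c("healthy", "not_healthy", "missing"))
    for (w in c("working", "not_working", "missing"))
      expect_length(encode_state(h, w, "alive"), 1)
})

test_that("arthritis is irreversible with nearest-wave imputation first", {
  expect_equal(enforce_arthritis_irreversibility(c("no", "yes", "no", NA)),
               c(0L, 1L, 1L, 1L))
  expect_equal(enforce_arthritis_irreversibility(c(NA, NA, "yes")),
               c(1L, 1L, 1L))
  expect_equal(enforce_arthritis_irreversibility(c("no", "no", "no")),
               c(0L, 0L, 0L))
  # tie in wave distance resolves to the earlier (no future information)
  expect_equal(enforce_arthritis_irreversibility(c("no", NA, "yes")),
               c(0L, 0L, 1L))
  expect_error(enforce_arthritis_irreversibility(c(NA, NA)), "excluded")
})

test_that("obesity is BMI >= 30 inclusive, in both unit systems", {
  expect_equal(compute_bmi_obesity(1.70, 86.7), 1L)    # BMI 30.0 exactly
  expect_equal(compute_bmi_obesity(1.70, 86.6), 0L)    # BMI 29.97
  expect_equal(compute_bmi_obesity(70, 180, "us"), 0L) # 703*180/4900 = 25.8
  expect_equal(compute_bmi_obesity(70, 215, "us"), 1L)  # BMI 30.8
  expect_warning(ob <- compute_bmi_obesity(0.9, 80), "implausible")
  expect_true(is.na(ob))
  expect_equal(compute_bmi_obesity(NA, 80), NA_integer_)
})

test_that("states map to the four census regions, DC included", {
  expect_equal(map_state_to_region("Illinois"), "Midwest")
  expect_equal(map_state_to_region("District of Columbia"), "South")
  expect_equal(map_state_to_region("Vermont"), "Northeast")
  expect_equal(map_state_to_region("Hawaii"), "West")
  expect_error(map_state_to_region("Puerto Rico"), "unknown")
  tab <- us_state_regions()
  expect_equal(nrow(tab), 51L)  # 50 states + DC
  expect_equal(sort(unique(tab$region)),
               c("Midwest", "Northeast", "South", "West"))
})

test_that("date imputation follows the June/December rules", {
  iv <- ym_parse(c("2008-05", "2010-08"))
  # missing death month, interview later that year: December
  d <- impute_dates(1940, 2, 2010, NA, iv)
  expect_equal(ym_format(d$death_m), "2010-12")
  # recorded month conflicts with a later interview the same year: December
  d <- impute_dates(1940, 2, 2010, 3, iv)
  expect_equal(ym_format(d$death_m), "2010-12")
  # missing month, no conflict: June
  d <- impute_dates(1940, 2, 2015, NA, iv)
  expect_equal(ym_format(d$death_m), "2015-06")
  # missing birth month: June
  expect_equal(ym_format(d$birth_m), "1940-02")
  d <- impute_dates(1940, NA, NA, NA, iv)
  expect_equal(ym_format(d$birth_m), "1940-06")
  # death record without a year is ignored
  expect_true(is.na(impute_dates(1940, 6, NA, 3, iv)$death_m))
  expect_error(impute_dates(1980, 6, 1975, 3, iv), "precedes")
})

test_that("nearest-wave imputation uses distance with earlier-wave ties", {
  expect_equal(impute_time_varying_nearest(c(1, NA, 0)), c(1, 1, 0))
  expect_equal(impute_time_varying_nearest(c(NA, NA, 1)), c(1, 1, 1))
  expect_equal(impute_time_varying_nearest(c(0, NA, NA, 1)), c(0, 0, 1, 1))
  expect_error(impute_time_varying_nearest(c(NA, NA)), "excluded")
})

test_that("longitudinal weight is the first non-zero at age 50 or older", {
  expect_equal(assign_longitudinal_weight(c(0, 3120, 2900), c(49, 51, 53)),
               3120)
  expect_true(is.na(assign_longitudinal_weight(c(500, 600), c(48, 49))))
  expect_true(is.na(assign_longitudinal_weight(c(0, 0, 0), c(51, 53, 55))))
  expect_error(assign_longitudinal_weight(c(-1, 2), c(51, 53)), "negative")
})

test_that("exclusion rules drop and log the right persons", {
  panel <- make_panel(list(
    list(date = c("2000-01", "2002-01"), age = c(55, 57), state = c(1, 2)),
    list(date = c("2000-01", "2002-01"), age = c(60, 62), state = c(3, 4))
  ))
  panel$region[panel$id == 2] <- NA
  ex <- apply_exclusions(panel)
  expect_equal(unique(ex$panel$id), 1L)
  expect_equal(ex$log$reason, "fixed_covariate:region")
  # time-varying covariate observed at some waves: retained
  panel2 <- make_panel(list(
    list(date = c("2000-01", "2002-01", "2004-01"), age = c(55, 57, 59),
         state = c(1, 1, 2), obese = c(NA, 1L, NA))))
  ex2 <- apply_exclusions(panel2)
  expect_equal(nrow(ex2$log), 0)
  # missing at all waves: dropped
  panel3 <- panel2
  panel3$obese <- NA_integer_
  ex3 <- apply_exclusions(panel3)
  expect_equal(ex3$log$reason, "time_varying_all_missing:obese")
  # empty input: empty output, empty log
  ex4 <- apply_exclusions(panel[0, ])
  expect_equal(nrow(ex4$panel), 0)
  expect_equal(nrow(ex4$log), 0)
})

test_that("the raw-answers pipeline reproduces the generator's coded states", {
  cfg <- true_model_config(n_individuals = 150, seed = 71, n_waves = 6)
  co <- generate_cohort(cfg, emit = "answers")
  coded <- prepare_panel(co$raw)
  truthp <- co$panel
  key <- function(d) paste(d$id, d$date)
  common <- intersect(key(coded), key(truthp))
  expect_gt(length(common), 0.95 * nrow(truthp))
  m1 <- coded[match(common, key(coded)), ]
  m2 <- truthp[match(common, key(truthp)), ]
  expect_equal(m1$state, m2$state)
  expect_equal(m1$sex_female, m2$sex_female)
  expect_equal(m1$educ_hs, m2$educ_hs)
  expect_equal(m1$region, m2$region)
  expect_equal(m1$weight, m2$weight)
  expect_equal(m1$death_date, m2$death_date)
  expect_equal(m1$age, m2$age, tolerance = 1e-9)
  # obesity equal wherever the raw answer was observed (others imputed)
  same <- !is.na(m2$obese)
  expect_gt(mean(m1$obese[same] == m2$obese[same]), 0.99)
})

test_that("prep output satisfies its postconditions and is idempotent", {
  cfg <- true_model_config(n_individuals = 100, seed = 72, n_waves = 6)
  co <- generate_cohort(cfg, emit = "answers")
  coded <- prepare_panel(co$raw)
  expect_true(all(coded$age >= 50 | is.na(coded$age)))
  by_id <- split(coded, coded$id)
  expect_true(all(vapply(by_id, function(d) {
    a <- d$arthritis[!is.na(d$arthritis)]
    all(diff(a) >= 0)
  }, logical(1))))
  part <- coded$state != -2
  expect_false(anyNA(coded$arthritis[part]))
  expect_false(anyNA(coded$obese[part]))
  expect_true(all(coded$weight > 0))
  expect_identical(prepare_panel(coded), coded)
})

test_that("a participated wave without an interview date is rejected", {
  cfg <- true_model_config(n_individuals = 10, seed = 73, n_waves = 3)
  raw <- generate_cohort(cfg, emit = "answers")$raw
  raw$interview_date[which(raw$participated)[1]] <- NA
  expect_error(prepare_panel(raw), "without an interview date")
})
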