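test_that("cohort CSV round-trips and empty cells stay missing", {
  coh <- make_cohort(
    id = c("a", "b", "c"), study = "s1",
    sex = c("male", "female", "female"),
    menopausal_status = c(NA, "premenopausal", "postmenopausal"),
    age = c(40, 30, 60), iron_intake = c(12.5, 9.1, 10.0),
    sf = c(150, NA, 60), crp = c(1.2, NA, 8),
    iron_supplement = c(FALSE, TRUE, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$individuals$iron_intake, coh$individuals$iron_intake)
  expect_equal(back$individuals$sf, coh$individuals$sf)
  expect_equal(back$individuals$iron_supplement,
               coh$individuals$iron_supplement)
  expect_true(is.na(back$individuals$sf[2]))          # missing, not zero
  expect_identical(back$individuals$menopausal_status[1], "not_applicable")
})

test_that("read_cohort enforces mandatory columns and numeric parsing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sex", "a,male"), path)
  expect_error(read_cohort(path), "iron_intake_mg_d")
  writeLines(c("id,sex,iron_intake_mg_d,sf_ug_l",
               "a,male,12,fifty"), path)
  expect_error(read_cohort(path), "row 1")
  expect_error(read_cohort(file.path(tempdir(), "nope.csv")), "not found")
})

test_that("custom column maps read arbitrary survey headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subj,gender,fe_mg,ferritin",
               "p1,male,11.5,130", "p2,female,8.2,25"), path)
  coh <- read_cohort(path, column_map = c(id = "subj", sex = "gender",
                                          iron_intake = "fe_mg",
                                          sf = "ferritin"))
  expect_equal(cohort_size(coh), 2)
  expect_equal(coh$individuals$sf, c(130, 25))
})

test_that("bundled example fixtures flow through the real readers", {
  coh <- read_cohort(system.file("extdata", "synthetic_cohort_example.csv",
                                 package = "ironavail"))
  expect_equal(cohort_size(coh), 12)
  dist <- load_requirement_table(
    system.file("extdata", "synthetic_requirements_premenopausal.csv",
                package = "ironavail"), group = "premenopausal")
  expect_length(dist$percentiles, 9)
})

test_that("exclusion pipeline filters sequentially and reports counts", {
  coh <- make_cohort(
    id = 1:7, sex = "male", iron_intake = 10,
    crp = c(6, NA, 1, NA, 2, 5, NA),       # 5 retained exactly at threshold
    act = c(NA, 0.7, NA, NA, 0.3, NA, NA), # absent markers retained
    sf = c(50, 50, NA, 60, 70, 80, 90),
    iron_supplement = c(FALSE, FALSE, FALSE, TRUE, NA, FALSE, FALSE))
  res <- apply_exclusions(coh)
  expect_equal(res$report$n_excluded_inflammation, 2)  # crp 6, act 0.7
  expect_equal(res$report$n_excluded_supplements, 1)
  expect_equal(res$report$n_excluded_missing_sf, 1)
  expect_equal(res$report$n_retained, 3)
  expect_setequal(res$cohort$individuals$id, c("5", "6", "7"))
  # conservation
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_excluded_inflammation +
                 res$report$n_excluded_supplements +
                 res$report$n_excluded_missing_sf)
})

test_that("exclusions are idempotent and identity on a clean cohort", {
  clean <- make_cohort(id = 1:3, sex = "male", iron_intake = 10,
                       sf = c(40, 50, 60))
  res1 <- apply_exclusions(clean)
  expect_equal(res1$report$n_retained, 3)
  expect_equal(res1$report$n_excluded_inflammation, 0)
  expect_equal(res1$cohort$individuals, clean$individuals)

  dirty <- nuage_margin_roster()
  once <- apply_exclusions(dirty)
  twice <- apply_exclusions(once$cohort)
  expect_equal(twice$cohort$individuals, once$cohort$individuals)
  expect_equal(twice$report$n_retained, once$report$n_retained)
})

test_that("stratify partitions by sex and menopausal status", {
  groups <- stratify(mixed_cohort())
  expect_named(groups, c("men", "premenopausal", "postmenopausal"))
  expect_equal(vapply(groups, cohort_size, integer(1)),
               c(men = 2L, premenopausal = 1L, postmenopausal = 1L))
  # all-male cohort leaves the women's cells empty
  men_only <- make_cohort(id = 1:2, sex = "male", iron_intake = 10)
  expect_equal(cohort_size(stratify(men_only)$premenopausal), 0)
  # female without classification is an error naming the id
  bad <- make_cohort(id = c("x", "y"), sex = c("male", "female"),
                     iron_intake = 10)
  expect_error(stratify(bad), "y")
})

test_that("combine_cohorts concatenates and disambiguates shared ids", {
  a <- make_cohort(id = c("1", "2"), sex = "male", iron_intake = 10,
                   label = "A")
  b <- make_cohort(id = c("2", "3"), sex = "male", iron_intake = 11,
                   label = "B")
  comb <- combine_cohorts(list(a, b))
  expect_equal(cohort_size(comb), 4)
  expect_setequal(comb$individuals$id, c("1", "A:2", "B:2", "3"))
  expect_error(combine_cohorts(list()), "no cohorts")
  # single-cohort combine is the identity up to provenance
  one <- combine_cohorts(list(a))
  expect_equal(one$individuals, a$individuals)
})

test_that("stratify then combine reproduces the multiset of individuals", {
  coh <- mixed_cohort()
  back <- combine_cohorts(unname(stratify(coh)))
  expect_setequal(back$individuals$id, coh$individuals$id)
  expect_equal(cohort_size(back), cohort_size(coh))
})

test_that("group_summary gives per-variable means and n-1 SDs", {
  coh <- make_cohort(id = 1:3, sex = "male", iron_intake = c(10, 12, 14),
                     sf = c(100, NA, 120))
  s <- suppressMessages(group_summary(coh))
  intake <- s[s$variable == "iron_intake", ]
  expect_equal(intake$mean, 12)
  expect_equal(intake$sd, 2)
  sf <- s[s$variable == "sf", ]
  expect_equal(sf$n_obs, 2)          # per-variable availability
  age <- s[s$variable == "age", ]
  expect_equal(age$n_obs, 0)         # absent for all: reported absent
  expect_true(is.na(age$mean))
})

test_that("generated summary agrees with the direct mean of drawn values", {
  spec <- group_spec("men", n = 20000, intake_mean = 13.8, intake_sd = 5.7,
                     sf_mean = 172, sf_sd = 135, seed = 11, study = "NANS")
  coh <- generate_group(spec)
  s <- suppressMessages(group_summary(coh))
  intake <- s[s$variable == "iron_intake", ]
  expect_equal(intake$mean, mean(cohort_intakes(coh)))
  expect_lt(abs(intake$mean - 13.8), 2 * 5.7 / sqrt(20000))
})

test_that("pooled mean and SD match direct computation on raw data", {
  x <- c(rnorm(30, 10, 2), rnorm(50, 13, 3))
  m <- c(mean(x[1:30]), mean(x[31:80]))
  s <- c(sd(x[1:30]), sd(x[31:80]))
  expect_equal(pooled_mean(m, c(30, 50)), mean(x))
  expect_equal(pooled_sd(m, s, c(30, 50)), sd(x))
  expect_equal(pooled_mean(7.3, 12), 7.3)
  expect_error(pooled_mean(numeric(), integer()), "empty")
})

test_that("SF cumulative distribution counts strictly below each cutoff", {
  coh <- make_cohort(id = 1:3, sex = "male", iron_intake = 10,
                     sf = c(10, 20, 30))
  cdf <- sf_cumulative_distribution(coh, cutoffs = c(5, 15, 20, 35))
  expect_equal(cdf$prevalence_below, c(0, 100 / 3, 100 / 3, 100))
  # value at a cutoff sits on the not-below (sufficient) side
  expect_equal(cdf$prevalence_below[3], cdf$prevalence_below[2])
  # missing SF is an error: filters must run first
  coh2 <- make_cohort(id = 1:2, sex = "male", iron_intake = 10,
                      sf = c(10, NA))
  expect_error(sf_cumulative_distribution(coh2, 15), "missing")
})

test_that("SF CDF is non-decreasing and permutation-invariant", {
  set.seed(5)
  sf <- rlnorm(200, 4, 0.8)
  coh <- make_cohort(id = seq_along(sf), sex = "male", iron_intake = 10,
                     sf = sf)
  cuts <- c(15, 20, 30, 40, 50, 60, 80, 100)
  cdf <- sf_cumulative_distribution(coh, cuts)
  expect_true(all(diff(cdf$prevalence_below) >= 0))
  perm <- sample(length(sf))
  coh2 <- make_cohort(id = seq_along(sf), sex = "male", iron_intake = 10,
                      sf = sf[perm])
  expect_equal(sf_cumulative_distribution(coh2, cuts)$prevalence_below,
               cdf$prevalence_below)
})

test_that("exclusion report serialises to JSON with per-stage counts", {
  res <- apply_exclusions(nuage_margin_roster())
  path <- withr::local_tempfile(fileext = ".json")
  write_exclusion_report(res$report, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$n_retained, res$report$n_retained)
  expect_length(back$excluded_ids$inflammation,
                res$report$n_excluded_inflammation)
})
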