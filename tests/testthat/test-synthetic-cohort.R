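# Cohort generator: lognormal calibration, exact class counts, seed
# determinism, CSV round-trip.

test_that("lognormal calibration reproduces the printed median and IQR", {
  # frozen from inverting the lognormal quantile function by hand:
  # mu = ln 16.7, sigma = (ln 89.2 - ln 4.7) / (2 * 0.6744898)
  f <- fit_lognormal_from_quantiles(16.7, 4.7, 89.2)
  expect_equal(f$mu, 2.8154087194, tolerance = 1e-9)
  expect_equal(f$sigma, 2.1818852918, tolerance = 1e-9)
  expect_false(f$degenerate)
  # fitted median is exact; fitted IQR has the requested log-width
  expect_equal(qlnorm(0.5, f$mu, f$sigma), 16.7, tolerance = 1e-12)
  expect_equal(qlnorm(0.75, f$mu, f$sigma) / qlnorm(0.25, f$mu, f$sigma),
               89.2 / 4.7, tolerance = 1e-9)
})

test_that("log-symmetric triples are reproduced at all three quantiles", {
  set.seed(41)
  for (i in 1:25) {
    med <- exp(stats::rnorm(1))
    r <- exp(abs(stats::rnorm(1)))
    f <- fit_lognormal_from_quantiles(med, med / r, med * r)
    q <- qlnorm(c(0.25, 0.5, 0.75), f$mu, f$sigma)
    expect_equal(q, c(med / r, med, med * r), tolerance = 1e-9)
  }
})

test_that("degenerate and invalid quantile triples are handled", {
  f <- fit_lognormal_from_quantiles(1, 1, 1)
  expect_equal(c(f$mu, f$sigma), c(0, 0))
  expect_true(f$degenerate)
  expect_error(fit_lognormal_from_quantiles(-1, 1, 2), "positive")
  expect_error(fit_lognormal_from_quantiles(0, 1, 2), "positive")
  expect_error(fit_lognormal_from_quantiles(2, 3, 4), "q1 <= median")
  expect_error(fit_lognormal_from_quantiles(2, 3, 3), "q1 <= median")
})

test_that("generated cohorts have exact class counts and pass invariants", {
  spec <- discovery_cohort_spec(seed = 7)
  co <- generate_cohort(spec)
  expect_equal(nrow(co), 40L)
  expect_equal(sum(co$infected), 21L)
  expect_equal(sum(!co$infected), 19L)
  expect_false(anyDuplicated(co$id) > 0)
  expect_true(all(co$nihss == round(co$nihss)))
  expect_true(all(co$nihss >= 0 & co$nihss <= 42))
  num <- c("age", "temperature", "saa", "crp", "pct", "wbc", "monocytes")
  expect_true(all(vapply(co[num], function(x) all(is.finite(x)), TRUE)))
  expect_true(all(co$saa > 0))
  expect_true(all(co$crp >= 3))  # detection floor
  expect_true(all(co$sex %in% c("female", "male")))
})

test_that("cohorts are a pure function of (spec, seed)", {
  spec <- validation_cohort_spec(seed = 3)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(as.data.frame(a), as.data.frame(b))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(a, f1); write_cohort_csv(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  d <- generate_cohort(spec, seed = 4)
  expect_false(identical(a$saa, d$saa))
})

test_that("empty cohorts and missing marker specs are handled", {
  spec <- discovery_cohort_spec()
  empty <- cohort_spec("discovery", 0L, 0L, spec$markers, seed = 1)
  co <- generate_cohort(empty)
  expect_equal(nrow(co), 0L)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  lines <- readLines(f)
  expect_length(lines, 1L)
  expect_match(lines, "^id,subgroup,infected,age,sex,nihss,temperature,saa,crp,pct,wbc,monocytes")
  crippled <- spec
  crippled$markers$saa <- NULL
  expect_error(generate_cohort(crippled), "saa")
})

test_that("empirical class-conditional medians converge to the spec", {
  spec <- validation_cohort_spec(seed = 11)
  big <- spec
  big$n_total <- 20000L
  big$n_infected <- 10000L
  co <- generate_cohort(big, seed = 11)
  saa_inf <- median(co$saa[co$infected])
  wbc_inf <- median(co$wbc[co$infected])
  nihss_non <- median(co$nihss[!co$infected])
  expect_lt(abs(saa_inf - 16.7) / 16.7, 0.05)
  expect_lt(abs(wbc_inf - 9.77) / 9.77, 0.05)
  expect_lt(abs(nihss_non - 4) / 4, 0.15)  # discretization coarsens this one
})

test_that("cohort CSV round-trips exactly and validates on read", {
  co <- generate_cohort(discovery_cohort_spec(seed = 5))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  for (col in names(co)) {
    expect_equal(back[[col]], co[[col]], tolerance = 0, label = col)
  }
  expect_equal(as.integer(back$nihss), as.integer(co$nihss))

  # missing cells survive as NA
  co2 <- co
  co2$saa[3] <- NA
  write_cohort_csv(co2, f)
  expect_true(is.na(read_cohort_csv(f)$saa[3]))

  # fractional NIHSS is a contract violation, named row and column
  lines <- readLines(f)
  lines[2] <- sub("^(([^,]*,){5})[^,]*", "\\13.7", lines[2])
  writeLines(lines, f)
  expect_error(read_cohort_csv(f), "nihss.*row 1|row 1.*nihss")

  # unknown columns warn but survive
  write_cohort_csv(co, f)
  lines <- readLines(f)
  lines[1] <- paste0(lines[1], ",mystery")
  lines[-1] <- paste0(lines[-1], ",1.5")
  writeLines(lines, f)
  expect_warning(back <- read_cohort_csv(f), "mystery")
  expect_equal(back$mystery[1], 1.5)

  # non-numeric marker cell names row and column
  write_cohort_csv(co, f)
  lines <- readLines(f)
  lines[3] <- sub("^(([^,]*,){7})[^,]*", "\\1oops", lines[3])
  writeLines(lines, f)
  expect_error(read_cohort_csv(f), "saa.*row 2|row 2.*saa")
})

test_that("cohort spec JSON round-trips", {
  for (spec in list(discovery_cohort_spec(seed = 2),
                    validation_cohort_spec(seed = 2))) {
    f <- tempfile(fileext = ".json")
    write_cohort_spec_json(spec, f)
    back <- read_cohort_spec_json(f)
    expect_equal(back, spec)
    expect_identical(as.data.frame(generate_cohort(back, 9)),
                     as.data.frame(generate_cohort(spec, 9)))
  }
})
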