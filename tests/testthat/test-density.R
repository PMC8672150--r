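# The dip statistic and its null calibration, and the taut-string density.

test_that("dip statistic matches the exact feasibility oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    x <- sort(runif(n))
    expect_equal(dip_test(x)$statistic, oracle_dip(x), tolerance = 1e-7)
  }
  # structured shapes
  for (x in list(bimodal_sample(60, seed = 1), rnorm(80),
                 c(rnorm(30), rnorm(10, 4)), rexp(50))) {
    expect_equal(dip_test(x)$statistic, oracle_dip(x), tolerance = 1e-7)
  }
})

test_that("dip hand values and the 1/(2n) lower bound hold", {
  # equispaced points admit a perfect linear unimodal fit
  expect_equal(dip_test(c(1, 2, 3, 4))$statistic, 1 / 8, tolerance = 1e-12)
  # two point masses approach the maximal dip of 1/4
  expect_equal(dip_test(c(0, 0.001, 1, 1.001))$statistic, 0.24975,
               tolerance = 1e-6)
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:200, 1)
    x <- rnorm(n)
    expect_gte(dip_test(x)$statistic, 1 / (2 * n) - 1e-12)
    expect_lte(dip_test(x)$statistic, 0.25)
  }
})

test_that("dip p-values separate uniform from strongly bimodal data", {
  set.seed(11)
  # perfectly uniform grid: high p-value
  expect_gt(dip_test(seq(0, 1, length.out = 1000))$p_value, 0.25)
  # two far components: decisive rejection
  x <- c(rnorm(500, 0), rnorm(500, 8))
  expect_lt(dip_test(x)$p_value, 0.01)
  # n below 4 is an explicit error (callers treat it as unimodal)
  expect_error(dip_test(c(1, 2, 3)), "insufficient")
})

test_that("dip p-values are approximately uniform under a uniform null", {
  set.seed(23)
  p <- replicate(200, dip_test(runif(100))$p_value)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(p > 0.25), 0.5)   # most uniform draws look unimodal
})

test_that("taut string matches the energy-minimization oracle", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(30:90, 1)
    x <- sort(c(rnorm(n %/% 2), rnorm(n - n %/% 2, 4)))
    r <- runif(1, 0.03, 0.15)
    d <- taut_string_density(x, radius = r)
    v <- approx(d$breakpoints, c(0, cumsum(d$heights * diff(d$breakpoints))),
                xout = x)$y
    expect_equal(v, oracle_taut_string(x, r), tolerance = 5e-5)
  }
})

test_that("taut string density integrates to one and alternates modes", {
  set.seed(37)
  for (x in list(rnorm(2000), bimodal_sample(2000),
                 c(rnorm(900), rnorm(600, 5), rnorm(500, 10)))) {
    d <- taut_string_density(x)
    expect_equal(sum(d$heights * diff(d$breakpoints)), 1, tolerance = 1e-9)
    expect_true(all(d$heights >= 0))
    expect_equal(nrow(d$antimodes), nrow(d$modes) - 1)
  }
})

test_that("taut string recovers the modal structure of clean mixtures", {
  set.seed(41)
  d1 <- taut_string_density(rnorm(5000))
  expect_identical(nrow(d1$modes), 1L)
  d2 <- taut_string_density(bimodal_sample(5000))
  expect_identical(nrow(d2$modes), 2L)
  expect_identical(nrow(d2$antimodes), 1L)
  expect_true(d2$antimodes[1, 1] < 4 && 4 < d2$antimodes[1, 2])
})

test_that("taut string is translation equivariant and radius-monotone", {
  set.seed(43)
  x <- bimodal_sample(600)
  d0 <- taut_string_density(x)
  d1 <- taut_string_density(x + 17.5)
  expect_equal(d1$breakpoints, d0$breakpoints + 17.5, tolerance = 1e-9)
  expect_equal(d1$heights, d0$heights, tolerance = 1e-9)
  # mode count nonincreasing in the tube radius
  x3 <- c(rnorm(800), rnorm(500, 4), rnorm(700, 9))
  nm <- sapply(c(0.005, 0.02, 0.05, 0.1, 0.2),
               function(r) nrow(taut_string_density(x3, radius = r)$modes))
  expect_true(all(diff(nm) <= 0))
  expect_error(taut_string_density(rep(1, 100)), "degenerate")
  expect_error(taut_string_density(rnorm(10)), "at least 25")
})

test_that("gates sit at antimode midpoints, sorted", {
  d <- structure(list(antimodes = matrix(c(3.8, 4.2), 1),
                      modes = matrix(0, 2, 2)),
                 class = "taut_string_density")
  expect_equal(gates_from_density(d), 4)
  d$antimodes <- matrix(numeric(0), 0, 2)
  expect_identical(gates_from_density(d), numeric(0))
  d$antimodes <- matrix(c(6, 1, 8, 2), 2)   # rows (6,8) and (1,2)
  expect_equal(gates_from_density(d), c(1.5, 7))
})

test_that("the benchmark gate lands between the 0 and 8 components", {
  set.seed(53)
  hits <- replicate(25, {
    x <- c(rnorm(600, 0, sqrt(runif(1, 1, 2))), rnorm(400, 8, sqrt(runif(1, 1, 2))))
    g <- gates_from_density(taut_string_density(x))
    length(g) == 1 && g > 2.5 && g < 5.5
  })
  expect_gt(mean(hits), 0.95)
})

test_that("trimmed L-moment ratios match the subset-expectation oracle", {
  set.seed(61)
  for (rep in 1:4) {
    x <- rnorm(11)
    expect_equal(trimmed_lmoment_ratios(x), oracle_tlmoments(x), tolerance = 1e-10)
  }
  x <- rexp(12)
  expect_equal(trimmed_lmoment_ratios(x), oracle_tlmoments(x), tolerance = 1e-10)
  # exact symmetry kills the skewness ratio
  y <- c(-5, -2, -1, 1, 2, 5, 0, -0.5, 0.5)
  expect_equal(trimmed_lmoment_ratios(y)[["tau3"]], 0, tolerance = 1e-12)
})

test_that("densities export as breakpoint-height tables", {
  set.seed(67)
  d <- taut_string_density(rnorm(200))
  df <- as.data.frame(d)
  expect_identical(colnames(df), c("breakpoint", "height"))
  expect_identical(nrow(df), length(d$heights))
})
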