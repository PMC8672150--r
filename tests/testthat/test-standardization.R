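# Cross-unit standardization of annotation boundaries.

test_that("gate-count vote takes the mode, ties the smaller count", {
  expect_identical(vote_gate_count(c(1, 1, 1, 2)), 1L)
  expect_identical(vote_gate_count(c(1, 2)), 1L)
  expect_identical(vote_gate_count(c(2, 2, 3, 3)), 2L)
  expect_identical(vote_gate_count(c(1, 1, 1), override = 2), 2L)
})

test_that("standards are rank-wise medians over conforming units", {
  expect_equal(compute_standards(list(3.9, 4.0, 4.3), 1), 4.0)
  expect_equal(compute_standards(list(c(1, 5), c(2, 6)), 2), c(1.5, 5.5))
  expect_equal(compute_standards(list(c(2, 7)), 2), c(2, 7))
  # non-conforming units are ignored
  expect_equal(compute_standards(list(c(1, 5), 4.2, c(2, 6)), 2), c(1.5, 5.5))
  expect_error(compute_standards(list(c(1, 2)), 3), "no conforming unit")
})

test_that("reconcile matches by distance, imputes and deletes", {
  # single boundary 4.1 against standards (1.5, 5.5): 4.1 is nearer 5.5
  r <- reconcile_unit(4.1, c(1.5, 5.5))
  expect_equal(r$locations[2], 4.1)
  expect_identical(r$provenance, c("imputed", "estimated"))
  # the imputed slot carries the unit's mean signed offset (4.1 - 5.5)
  expect_equal(r$locations[1], 1.5 + (4.1 - 5.5))

  # surplus boundaries farthest from the single standard are deleted
  r2 <- reconcile_unit(c(1, 4, 7), 4.0)
  expect_equal(r2$locations, 4)
  expect_identical(r2$n_deleted, 2L)

  # idempotence on conforming input
  r3 <- reconcile_unit(c(1.5, 5.5), c(1.5, 5.5))
  expect_equal(r3$locations, c(1.5, 5.5))
  expect_identical(r3$provenance, c("estimated", "estimated"))
  r3b <- reconcile_unit(r3$locations, c(1.5, 5.5))
  expect_equal(r3b$locations, r3$locations)

  # missing unit: all standards imputed verbatim
  r4 <- reconcile_unit(NULL, c(2, 8))
  expect_equal(r4$locations, c(2, 8))
  expect_identical(r4$provenance, c("imputed", "imputed"))

  # greedy minimal-distance matching agrees with exhaustive assignment on
  # random instances
  set.seed(83)
  for (rep in 1:20) {
    k <- sample(1:4, 1); nb <- sample(1:4, 1)
    s <- sort(runif(k, 0, 10)); b <- sort(runif(nb, 0, 10))
    r <- reconcile_unit(b, s)
    expect_length(r$locations, k)
    expect_true(all(diff(r$locations) > 0))
    expect_identical(sum(r$provenance == "estimated"), min(k, nb))
    # every estimated location is one of the unit's boundaries
    expect_true(all(r$locations[r$provenance == "estimated"] %in% b))
  }
})

test_that("flat-hierarchy standardization equals single-pass behavior", {
  ub <- list(u1 = list(A = 3.9), u2 = list(A = 4.0), u3 = list(A = c(1, 4.3)))
  spec <- standardize_all(ub, "A")
  expect_identical(spec$spec$A$k_star, 1L)
  expect_equal(spec$spec$A$standards, median(c(3.9, 4.0)))
  # all units end with exactly k* boundaries
  for (u in names(ub))
    expect_length(spec$spec$A$units[[u]]$locations, 1)
  # conforming units keep their own estimates
  expect_equal(spec$spec$A$units$u1$locations, 3.9)
  expect_identical(spec$spec$A$units$u3$provenance, "estimated")
})

test_that("two-pass hierarchy imputes within class first, then globally", {
  # marker estimated only in class X; class-Y units draw standards from X
  ub <- list(u1 = list(A = 3.0), u2 = list(A = 5.0),
             u3 = list(A = NULL), u4 = list(A = NULL))
  h <- c(u1 = "X", u2 = "X", u3 = "Y", u4 = "Y")
  spec <- standardize_all(ub, "A", hierarchy = h)
  expect_equal(spec$spec$A$units$u3$locations, 4.0)  # global standard
  expect_identical(spec$spec$A$units$u3$provenance, "imputed")
  # class-X units reconcile against their class standards (their own values)
  expect_equal(spec$spec$A$units$u1$locations, 3.0)

  # hierarchy classes with conforming members use class-local standards
  ub2 <- list(u1 = list(A = 2.0), u2 = list(A = 2.4),
              u3 = list(A = 7.0), u4 = list(A = NULL))
  h2 <- c(u1 = "X", u2 = "X", u3 = "Y", u4 = "Y")
  spec2 <- standardize_all(ub2, "A", hierarchy = h2)
  expect_equal(spec2$spec$A$units$u4$locations, 7.0)  # class-Y standard
})

test_that("supervised overrides bypass the vote", {
  ub <- list(u1 = list(A = 4.0), u2 = list(A = 4.4), u3 = list(A = c(2, 6)))
  spec <- standardize_all(ub, "A", overrides = list(A = list(count = 2)))
  expect_identical(spec$spec$A$k_star, 2L)
  expect_length(spec$spec$A$units$u1$locations, 2)
  spec2 <- standardize_all(ub, "A",
                           overrides = list(A = list(count = 1, locations = 5)))
  expect_equal(spec2$spec$A$standards, 5)

  expect_error(standardize_all(list(u1 = list(A = NULL)), "A"), "never gated")
})

test_that("post-standardization gate counts are constant across units", {
  set.seed(89)
  for (rep in 1:10) {
    units <- paste0("u", 1:6)
    ub <- lapply(units, function(u) {
      k <- sample(0:3, 1)
      list(A = if (k > 0) sort(runif(k, 0, 10)) else NULL,
           B = sort(runif(2, 0, 10)))
    })
    names(ub) <- units
    if (all(sapply(ub, function(x) is.null(x$A)))) next
    spec <- standardize_all(ub, c("A", "B"))
    for (m in c("A", "B")) {
      lens <- sapply(units, function(u) length(spec$spec[[m]]$units[[u]]$locations))
      expect_true(all(lens == spec$spec[[m]]$k_star))
      # conforming units' estimated boundaries are never moved by imputation
      for (u in units) {
        b <- ub[[u]][[m]]
        if (!is.null(b) && length(b) == spec$spec[[m]]$k_star)
          expect_true(all(spec$spec[[m]]$units[[u]]$locations %in% b))
      }
    }
  }
})
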