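# Partition trees, shape scoring, leaf selection, annotation.

twocluster_em <- function(n = 2000, seed = 97) {
  set.seed(seed)
  cl <- rep(1:2, length.out = n)
  v <- cbind(A = rnorm(n, c(0, 8)[cl]), B = rnorm(n))
  list(em = expression_matrix(v, sample_id = "u"), cl = cl)
}

wide_bounds <- function(markers) {
  b <- rbind(low = rep(-50, length(markers)), high = rep(50, length(markers)))
  colnames(b) <- markers
  b
}

test_that("partition trees partition the unit and are seed-deterministic", {
  d <- twocluster_em()
  b <- wide_bounds(c("A", "B"))
  set.seed(5); t1 <- grow_partition_tree(d$em, c("A", "B"), b)
  set.seed(5); t2 <- grow_partition_tree(d$em, c("A", "B"), b)
  expect_identical(t1, t2)
  expect_identical(sort(unlist(t1)), seq_len(nrow(d$em$values)))

  # clean two-cluster structure: leaves align with the components
  leaf_of <- integer(nrow(d$em$values))
  for (i in seq_along(t1)) leaf_of[t1[[i]]] <- i
  expect_gt(adjusted_rand_index(leaf_of, d$cl), 0.95)
})

test_that("a unimodal margin yields a single leaf", {
  set.seed(101)
  v <- cbind(A = rnorm(500), B = rnorm(500))
  em <- expression_matrix(v, sample_id = "u")
  set.seed(1)
  tr <- grow_partition_tree(em, "A", wide_bounds(c("A", "B")))
  expect_length(tr, 1)
  expect_identical(sort(tr[[1]]), 1:500)
})

test_that("shape score follows its multiplicative definition", {
  set.seed(103)
  leaf <- cbind(A = rnorm(200), B = rnorm(200))
  s <- shape_score(leaf)
  # direct arithmetic recomputation
  u <- 1
  for (j in 1:2) {
    tl <- trimmed_lmoment_ratios(leaf[, j])
    u <- u * dip_test(leaf[, j])$p_value * exp(-abs(tl[["tau3"]])) *
      exp(-abs(tl[["tau4"]] - 0.1226))
  }
  expect_equal(s, 200 * u, tolerance = 1e-12)

  # a strongly bimodal margin collapses the score
  leaf2 <- cbind(A = bimodal_sample(200), B = rnorm(200))
  expect_lt(shape_score(leaf2), s / 10)
  # tiny leaves score zero
  expect_identical(shape_score(leaf[1:4, , drop = FALSE]), 0)
})

test_that("greedy leaf selection is disjoint and matches brute force on toys", {
  # one tree: its leaves are already disjoint, all selected
  leaves <- list(1:10, 11:25, 26:30)
  sel <- select_leaves(leaves, c(5, 3, 1), 30)
  expect_setequal(sel, 1:3)
  # duplicated tree: exactly one copy of each leaf survives
  sel2 <- select_leaves(c(leaves, leaves), c(5, 3, 1, 5, 3, 1), 30)
  expect_length(sel2, 3)
  expect_setequal(lapply(c(leaves, leaves)[sel2], sort), leaves)

  # toy instance: greedy equals exhaustive maximum over disjoint subsets
  lv <- list(1:6, 4:10, 7:12, 1:3)
  sc <- c(10, 9, 8, 2)
  sel3 <- select_leaves(lv, sc, 12)
  best <- 0; combos <- unlist(lapply(1:4, function(k) combn(4, k, simplify = FALSE)), FALSE)
  for (cc in combos) {
    if (length(unlist(lv[cc])) == length(unique(unlist(lv[cc]))))
      best <- max(best, sum(sc[cc]))
  }
  expect_equal(sum(sc[sel3]), best)
  # disjointness always holds
  expect_identical(anyDuplicated(unlist(lv[sel3])), 0L)
})

test_that("leaf and cell annotation respect boundaries and the tie rule", {
  thr <- list(A = 4.0, B = c(3.0, 6.0))
  leaf <- cbind(A = rep(2, 30), B = rep(5, 30))
  expect_identical(annotate_leaf(leaf, thr), "A- Bdim")
  leaf2 <- cbind(A = rep(4.0, 30), B = rep(7, 30))   # exactly on the boundary
  expect_identical(annotate_leaf(leaf2, thr), "A- Bbright")

  cells <- cbind(A = c(2, 9, 4), B = c(9, 1, 3))
  ann <- annotate_cells(cells, thr)
  expect_identical(ann$labels,
                   c("A- Bbright", "A+ B-", "A- B-"))
  expect_identical(ann$levels[, "A"], c(1L, 2L, 1L))
  # every cell gets exactly one label; counts conserve cells
  expect_identical(length(ann$labels), 3L)
  v <- matrix(rep(c(2, 9), each = 10), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  annb <- annotate_cells(v, thr)
  expect_identical(length(unique(annb$labels)), 1L)
})

test_that("discover_unit finds the true phenotypes of a clean mixture", {
  d <- twocluster_em(n = 3000)
  b <- wide_bounds(c("A", "B"))
  thr <- list(A = 4.0, B = 0)  # B unimodal: give it a nominal boundary
  disc <- discover_unit(d$em, c("A", "B"), b,
                        thresholds = list(A = 4.0, B = 99),  # B always "-"
                        n_trees = 5, seed = 11)
  expect_true(all(c("A- B-", "A+ B-") %in% disc$phenotypes))
  # selected leaves disjoint
  expect_identical(anyDuplicated(unlist(disc$selected)), 0L)
  # determinism
  disc2 <- discover_unit(d$em, c("A", "B"), b,
                         thresholds = list(A = 4.0, B = 99),
                         n_trees = 5, seed = 11)
  expect_identical(disc$phenotypes, disc2$phenotypes)
})

test_that("level labels extend with the number of boundaries", {
  expect_identical(level_labels(1), c("-", "+"))
  expect_identical(level_labels(2), c("-", "dim", "bright"))
  expect_length(level_labels(3), 4)
  expect_length(level_labels(4), 5)
  expect_error(level_labels(5))
})
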