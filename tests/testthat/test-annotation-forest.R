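# Annotation forest growth, depth scores, marker selection, unit boundaries.

make_forest <- function(records, d = NULL, Pm, n_root = 1000,
                        markers = names(Pm)) {
  depths <- vapply(records, `[[`, 0L, "depth")
  if (is.null(d)) d <- vapply(0:2, function(q) sum(depths == q), 0L)
  structure(list(records = records, d = d, Pm = Pm, n_root = n_root,
                 unit_id = "u1", active_markers = markers,
                 params = list()),
            class = "annotation_forest")
}

test_that("node quality is the product of (1 - dip p) along the strategy", {
  expect_identical(node_quality(c(0.25, 0.25, 0.25)), 27 / 64)
  expect_equal(node_quality(c(0.25, 0.25, 0.25)), 0.421875)
  expect_equal(node_quality(c(0.1, 0.2)), 0.72)
  expect_equal(node_quality(1e-12), 1, tolerance = 1e-9)
  expect_error(node_quality(numeric(0)), "1 to 3")
  expect_error(node_quality(rep(0.1, 4)), "1 to 3")
  expect_error(node_quality(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("annotation forest matches a direct recursive enumeration", {
  # two strongly bimodal markers; small scale so the oracle enumeration is cheap
  set.seed(71)
  n <- 2000
  cl <- sample(1:4, n, replace = TRUE)
  v <- cbind(A = rnorm(n, c(0, 0, 8, 8)[cl]), B = rnorm(n, c(0, 8, 0, 8)[cl]))
  em <- expression_matrix(v, sample_id = "u1")
  bounds <- rbind(low = c(-50, -50), high = c(50, 50))
  colnames(bounds) <- c("A", "B")
  fr <- grow_annotation_forest(em, c("A", "B"), bounds, min_events = 200,
                               max_depth = 3)

  # independent enumeration written from the procedure definition
  oracle_records <- list()
  enumerate <- function(idx, path, depth) {
    if (depth >= 3 || length(idx) < 200) return(invisible())
    for (m in setdiff(c("A", "B"), path)) {
      x <- v[idx, m]
      x <- x[x > bounds[1, m] & x < bounds[2, m]]
      if (length(x) < 25) next
      if (dip_test(x)$p_value >= 0.25) next
      g <- gates_from_density(taut_string_density(x))
      if (length(g) == 0 || length(g) > 4) next
      oracle_records[[length(oracle_records) + 1]] <<-
        list(marker = m, depth = depth, n = length(x), gates = g)
      grp <- findInterval(v[idx, m], g)
      for (gg in 0:length(g)) enumerate(idx[grp == gg], c(path, m), depth + 1)
    }
  }
  enumerate(seq_len(n), character(0), 0L)

  key <- function(r) sprintf("%s|%d|%d|%s", r$marker, r$depth,
                             if (is.null(r$n_eff)) r$n else r$n_eff,
                             paste(round(r$gates, 6), collapse = ","))
  expect_setequal(sapply(fr$records, key), sapply(oracle_records, key))
  expect_identical(fr$d, vapply(0:2, function(q)
    sum(sapply(oracle_records, `[[`, "depth") == q), 0L))
})

test_that("forest respects event-count preconditions", {
  set.seed(73)
  v <- cbind(A = bimodal_sample(400), B = rnorm(400))
  em <- expression_matrix(v, sample_id = "u")
  bounds <- rbind(low = c(-50, -50), high = c(50, 50)); colnames(bounds) <- c("A", "B")
  fr <- grow_annotation_forest(em, c("A", "B"), bounds, min_events = 500)
  expect_length(fr$records, 0)

  # a single active bimodal marker: depth-1 forest with one gated marker
  v2 <- cbind(A = bimodal_sample(2000), B = rnorm(2000))
  em2 <- expression_matrix(v2, sample_id = "u")
  fr2 <- grow_annotation_forest(em2, "A", bounds, min_events = 500)
  expect_gte(length(fr2$records), 1)
  expect_true(all(sapply(fr2$records, `[[`, "marker") == "A"))
  expect_true(all(sapply(fr2$records, `[[`, "depth") == 0))
})

test_that("depth scores equal the hand-computed omega ratios", {
  # hand-built forest: marker A gated at root (alpha .1) and in a child
  # (alphas .1, .2); marker B gated once at root (alpha .25)
  Pm <- c(A = 1000L, B = 800L)
  rec <- list(
    list(marker = "A", depth = 0L, alphas = 0.1, n_eff = 1000L, gates = 4),
    list(marker = "A", depth = 1L, alphas = c(0.1, 0.2), n_eff = 400L, gates = 4),
    list(marker = "B", depth = 0L, alphas = 0.25, n_eff = 800L, gates = 4))
  fr <- make_forest(rec, Pm = Pm)
  ds <- depth_scores(fr)
  # d = (2, 1, 0); omega_A = .9*1*(1/2) + .72*.4*1 = .738; omega_B = .75*1*.5
  expect_equal(ds$raw[ds$marker == "A"], 0.9 * 0.5 + 0.9 * 0.8 * 0.4 * 1)
  expect_equal(ds$raw[ds$marker == "B"], 0.75 * 0.5)
  expect_equal(ds$ds[ds$marker == "A"], 1)
  expect_equal(ds$ds[ds$marker == "B"], 0.375 / 0.738)

  # duplicating every record rescales raw scores but leaves DS unchanged
  fr2 <- make_forest(c(rec, rec), Pm = Pm)
  expect_equal(depth_scores(fr2)$ds, ds$ds)

  # a forest where only one marker is gated: that marker scores 1, others 0
  fr3 <- make_forest(rec[3], Pm = Pm)
  ds3 <- depth_scores(fr3)
  expect_equal(ds3$ds, c(0, 1)[match(ds3$marker, c("A", "B"))])
})

test_that("marker selection applies the quantile-threshold rule", {
  mk <- c("M1", "M2", "M3")
  mktab <- function(ds) structure(data.frame(marker = mk, raw = ds, ds = ds),
                                  class = c("depth_score_table", "data.frame"))
  tabs <- lapply(list(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0.02),
                      c(1, 0, 0.5), c(1, 0, 1)), mktab)
  sel <- select_markers(tabs, prob = 0.5, threshold = 0.01)
  expect_identical(sel, c("M1", "M3"))    # median of M3 = 0.02 > 0.01
  expect_identical(select_markers(tabs, prob = 0.5, threshold = 0.5), "M1")
})

test_that("unit boundary estimation picks the heaviest gate count", {
  Pm <- c(A = 1000L)
  # G1 nodes with omega 1*1*(1/3) each (three root records, alphas 0)
  rec <- list(
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 1000L, gates = 4.0),
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 1000L, gates = 4.0),
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 1000L, gates = 4.0))
  fr <- make_forest(rec, Pm = Pm, markers = "A")
  ub <- estimate_unit_boundaries(fr, depth_scores(fr), "A")
  expect_identical(ub$n_gates, 1L)
  expect_equal(ub$locations, 4.0)

  # weighted average: omegas proportional to n_eff (1, 3), gates 2 and 6
  rec2 <- list(
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 250L, gates = 2),
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 750L, gates = 6))
  fr2 <- make_forest(rec2, Pm = Pm, markers = "A")
  ub2 <- estimate_unit_boundaries(fr2, depth_scores(fr2), "A")
  expect_equal(ub2$locations, (0.25 * 2 + 0.75 * 6))

  # the gate count with larger total omega wins
  rec3 <- list(
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 700L, gates = 4),
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 450L, gates = c(2, 6)),
    list(marker = "A", depth = 0L, alphas = 0, n_eff = 450L, gates = c(3, 7)))
  fr3 <- make_forest(rec3, Pm = Pm, markers = "A")
  ub3 <- estimate_unit_boundaries(fr3, depth_scores(fr3), "A")
  expect_identical(ub3$n_gates, 2L)
  expect_equal(ub3$locations, c(2.5, 6.5))

  expect_null(estimate_unit_boundaries(fr3, depth_scores(fr3), "B"))
})

test_that("selected markers on the benchmark are the bimodal margins", {
  set.seed(79)
  # 4 clusters: markers M1-M3 bimodal across clusters, M4 constant at 8,
  # M5-M6 unimodal noise
  n <- 3000
  cl <- sample(1:4, n, replace = TRUE)
  mu <- rbind(c(0, 0, 8, 8), c(0, 8, 0, 8), c(8, 0, 0, 8), c(8, 8, 8, 8))
  v <- sapply(1:4, function(j) rnorm(n, mu[cl, j]))
  v <- cbind(v, rnorm(n, 4), rnorm(n, 0))   # unimodal margins
  colnames(v) <- sprintf("M%d", 1:6)
  em <- expression_matrix(v, sample_id = "u")
  bounds <- default_boundary_matrix(list(em))
  fr <- grow_annotation_forest(em, colnames(v), bounds, min_events = 300)
  ds <- depth_scores(fr)
  sel <- select_markers(list(ds))
  expect_setequal(sel, c("M1", "M2", "M3"))
})

test_that("forest summaries serialize to JSON", {
  set.seed(59)
  v <- cbind(A = bimodal_sample(1500), B = rnorm(1500))
  em <- expression_matrix(v, sample_id = "u")
  b <- rbind(low = c(-50, -50), high = c(50, 50)); colnames(b) <- c("A", "B")
  fr <- grow_annotation_forest(em, c("A", "B"), b, min_events = 400)
  s <- forest_summary(fr)
  expect_identical(s$unit, "u")
  expect_identical(sum(unlist(s$gatings_by_depth)), length(fr$records))
  expect_no_error(jsonlite::toJSON(s, auto_unbox = TRUE))
})
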