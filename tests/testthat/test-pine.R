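test_that("tree depth follows the resolution formula", {
  expect_equal(pine_depth(400, 400, 20), 1L)
  # exact power of the branching factor must not round up a level
  expect_equal(pine_depth(8000, 400, 400), 3L)
  expect_equal(pine_depth(400, 400, 1), 1L)   # resolution >= chromosome
  expect_equal(pine_depth(1e6, 1e6, 1000), 3L)
})

test_that("depth matches the exact-arithmetic oracle on random views", {
  set.seed(13)
  cfg <- pine_config()
  for (i in 1:10000) {
    L <- sample.int(1e7, 1)
    view <- sample.int(L, 1)
    px <- sample.int(2000, 1)
    expect_identical(pine_depth(L, view, px, cfg),
                     as.integer(bf_depth(L, view, px)),
                     info = sprintf("L=%d view=%d px=%d", L, view, px))
  }
})

test_that("depth is non-increasing as views coarsen", {
  set.seed(14)
  for (i in 1:200) {
    L <- sample.int(1e6, 1)
    px <- sample.int(1000, 1)
    v1 <- sample.int(L, 1); v2 <- min(L, v1 * sample(2:10, 1))
    expect_gte(pine_depth(L, v1, px), pine_depth(L, v2, px))
  }
})

test_that("partitioning is n-way, exact, and degrades below n bases", {
  p <- oakpine:::partition_span(0, 8000, 20)
  expect_equal(nrow(p), 20L)
  expect_equal(unique(p$right - p$left), 400)
  expect_equal(p$left[-1], p$right[-20])
  # non-multiple length still tiles exactly
  p2 <- oakpine:::partition_span(7, 7 + 133, 20)
  expect_equal(p2$left[1], 7)
  expect_equal(p2$right[nrow(p2)], 140)
  expect_true(all(p2$right > p2$left))
  expect_equal(p2$left[-1], p2$right[-nrow(p2)])
  # a span shorter than n yields one child per base
  p3 <- oakpine:::partition_span(0, 4, 20)
  expect_equal(nrow(p3), 4L)
})

test_that("structure building expands only query-overlapping lineages", {
  ci <- toy_chroms(chr1 = 400)
  # 1 bp/px over a 20 bp window: 400 = 20^2 so the tree reaches depth 2
  tree <- pine_build(ci, viewport("chr1", 0, 20, 20))
  expect_equal(tree$depth, 2L)
  kids <- tree$root$children
  expect_length(kids, 20L)
  expect_equal(vapply(kids, function(k) k$right - k$left, numeric(1)),
               rep(20, 20))
  ph <- vapply(kids, `[[`, logical(1), "placeholder")
  expect_identical(which(!ph), 1L)
  # only the overlapping lineage grows grandchildren
  expect_length(kids[[1]]$children, 20L)
  expect_true(all(vapply(kids[-1], function(k) is.null(k$children),
                         logical(1))))

  full <- pine_build(ci, viewport("chr1", 0, 400, 20))
  expect_false(any(vapply(full$root$children, `[[`, logical(1), "placeholder")))

  # depth 2, query hugging the right chromosome edge
  edge <- pine_build(ci, viewport("chr1", 390, 400, 10))
  expect_equal(edge$depth, 2L)
  top_ph <- vapply(edge$root$children, `[[`, logical(1), "placeholder")
  expect_identical(which(!top_ph), 20L)
  grand <- edge$root$children[[20]]$children
  gph <- vapply(grand, `[[`, logical(1), "placeholder")
  expect_equal(sum(!gph), 10L)  # bases 390..399 expanded, 380..389 not
})

test_that("summary merge is componentwise with empty identities", {
  a <- summary_stats(2, 3, 5, 2, 1)
  b <- summary_stats(3, 6, 14, 3, 1)
  m <- summary_merge(list(a, b))
  expect_equal(c(m$bases, m$sum_values, m$sum_squares, m$max_value, m$min_value),
               c(5, 9, 19, 3, 1))
  expect_equal(summary_merge(list(a, summary_empty())), a)
  # fold of per-base child summaries equals the base-level oracle
  set.seed(17)
  vals <- round(rlnorm(20), 3)
  parts <- lapply(vals, function(v) summary_stats(1, v, v^2, v, v))
  want <- bf_summary(vals, 0, 20)
  expect_equal(summary_merge(parts), want)
})

test_that("loading fills leaves then ancestors, idempotently", {
  ci <- toy_chroms(chr1 = 4)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", c(1, 2, 3, 4)))
  tree <- pine_build(ci, viewport("chr1", 0, 4, 4))
  pine_load(tree, be, "dense")
  r <- tree$root$summary
  expect_equal(c(r$bases, r$sum_values, r$sum_squares, r$max_value, r$min_value),
               c(4, 10, 30, 4, 1))
  n1 <- ledger_snapshot(be)$requests
  pine_load(tree, be, "dense")  # reload: nothing new to transfer
  expect_equal(ledger_snapshot(be)$requests, n1)
})

test_that("placeholder subtrees are never requested", {
  ci <- toy_chroms(chr1 = 400)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", rep(2, 400)))
  tree <- pine_build(ci, viewport("chr1", 0, 20, 20))
  pine_load(tree, be, "dense")
  log <- ledger_snapshot(be)$log
  expect_true(all(log$end <= 20))  # only the expanded child's span
})

test_that("a shifted view fetches exactly the uncovered spans", {
  ci <- toy_chroms(chr1 = 8000)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", rep(1, 8000)))
  tree <- pine_build(ci, viewport("chr1", 0, 400, 400))  # 1 bp/px, depth 3
  pine_load(tree, be, "dense")
  n0 <- ledger_snapshot(be)$requests
  pine_update(tree, viewport("chr1", 200, 600, 400), be, "dense")
  log <- ledger_snapshot(be)$log
  new_rows <- log[seq(n0 + 1, nrow(log)), , drop = FALSE]
  fetched <- oakpine:::iset_normalize(data.frame(start = new_rows$start,
                                                 end = new_rows$end))
  expect_equal(fetched, data.frame(start = 400, end = 600))
})

test_that("zooming in keeps coarse summaries and fetches only the new level", {
  ci <- toy_chroms(chr1 = 8000)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", rep(1, 8000)))
  tree <- pine_build(ci, viewport("chr1", 0, 8000, 400))  # 20 bp/px -> depth 2
  pine_load(tree, be, "dense")
  expect_equal(tree$depth, 2L)
  root_before <- tree$root$summary
  n0 <- ledger_snapshot(be)$requests
  pine_update(tree, viewport("chr1", 0, 400, 400), be, "dense")  # depth 3
  expect_equal(tree$depth, 3L)
  log <- ledger_snapshot(be)$log
  fresh <- log[seq(n0 + 1, nrow(log)), ]
  expect_true(all(fresh$level == 3L))
  expect_equal(tree$root$summary$bases, root_before$bases)
})

test_that("zooming out reuses deeper summaries instead of refetching", {
  ci <- toy_chroms(chr1 = 8000)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", rep(1, 8000)))
  ses_tree <- pine_build(ci, viewport("chr1", 0, 400, 400))  # depth 3
  pine_load(ses_tree, be, "dense")
  n0 <- ledger_snapshot(be)$requests
  pine_update(ses_tree, viewport("chr1", 0, 8000, 20), be, "dense")  # depth 1
  log <- ledger_snapshot(be)$log
  fresh <- log[seq(n0 + 1, nrow(log)), , drop = FALSE]
  # spans already summarized at finer levels are not re-fetched: every
  # new request lies outside the previously loaded (0,400) window
  expect_true(all(fresh$start >= 400))
  aud <- pine_audit(ses_tree)
  expect_true(aud$ok)
})

test_that("per-pixel profiles are exact on aligned toy signals", {
  ci <- toy_chroms(chr1 = 4)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chr1", c(1, 2, 3, 4)))
  v <- viewport("chr1", 0, 4, 2)
  tree <- pine_build(ci, v)
  pine_update(tree, v, be, "dense")
  prof <- pine_profile(tree, v)
  expect_equal(prof$mean, c(1.5, 3.5))
  expect_equal(prof$max, c(2, 4))
  expect_equal(prof$min, c(1, 3))

  # constant signal: every pixel mean is the constant
  ci2 <- toy_chroms(chr2 = 1000)
  be2 <- make_backend(ci2, bedgraph = make_base_bedgraph("chr2", rep(7, 1000)))
  v2 <- viewport("chr2", 0, 1000, 50)
  t2 <- pine_build(ci2, v2)
  pine_update(t2, v2, be2, "dense")
  expect_equal(unique(pine_profile(t2, v2)$mean), 7)

  # a pixel fully inside a data gap carries a gap marker
  ci3 <- toy_chroms(chr3 = 100)
  be3 <- make_backend(ci3, bedgraph = make_base_bedgraph("chr3", c(5, 5), offset = 0))
  v3 <- viewport("chr3", 0, 100, 10)
  t3 <- pine_build(ci3, v3)
  pine_update(t3, v3, be3, "dense")
  prof3 <- pine_profile(t3, v3)
  expect_false(prof3$gap[1])
  expect_true(all(prof3$gap[-1]))

  expect_error(pine_profile(pine_build(ci3, v3), v3), "update")
})

test_that("aggregation conservation holds after random operation sequences", {
  set.seed(19)
  ci <- toy_chroms(chrQ = 5000)
  vals <- round(rlnorm(5000), 3)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chrQ", vals))
  tree <- pine_build(ci, viewport("chrQ", 0, 5000, 100))
  pine_load(tree, be, "dense")
  for (i in 1:12) {
    s <- sample.int(4000, 1); w <- sample(c(100, 500, 2000), 1)
    pine_update(tree, viewport("chrQ", s, min(5000, s + w), 100), be, "dense")
    aud <- pine_audit(tree)
    expect_true(aud$ok)
    expect_lte(aud$max_rel_err, 1e-9)
  }
  # fully loaded root equals the backend's whole-chromosome summary
  root <- tree$root$summary
  whole <- fetch_summary(be, "dense", gi("chrQ", 0, 5000))
  expect_equal(root$bases, whole$bases)
  expect_equal(root$sum_values, whole$sum_values, tolerance = 1e-9)
  expect_equal(root$sum_squares, whole$sum_squares, tolerance = 1e-9)
  expect_equal(root$max_value, whole$max_value)
  expect_equal(root$min_value, whole$min_value)
})

test_that("no span is summarized twice at the same level while loaded", {
  set.seed(29)
  ci <- toy_chroms(chrQ = 5000)
  be <- make_backend(ci, bedgraph = make_base_bedgraph("chrQ", rep(1, 5000)))
  tree <- pine_build(ci, viewport("chrQ", 0, 500, 100))
  pine_load(tree, be, "dense")
  for (i in 1:8) {  # fewer queries than the eviction window: nothing unloads
    s <- sample.int(4500, 1)
    pine_update(tree, viewport("chrQ", s, s + 500, 100), be, "dense")
  }
  log <- ledger_snapshot(be)$log
  for (lv in unique(log$level)) {
    rows <- log[log$level == lv, ]
    span_sum <- sum(rows$end - rows$start)
    merged <- oakpine:::iset_normalize(data.frame(start = rows$start,
                                                  end = rows$end))
    expect_equal(span_sum, sum(merged$end - merged$start),
                 info = sprintf("level %s", lv))
    expect_lte(span_sum, 5000)
  }
})
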