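engine_fixture <- function(seed = 101) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- fixture_spec(seed = seed, chroms = c(chrI = 5000, chrII = 5000),
                       sparse_n = 120, dense_segments = 60, interaction_n = 40)
  gen_tracks(spec, dir)
  be <- data_backend(file.path(dir, "chrom.sizes"))
  backend_add_track(be, "peaks", "sparse", file.path(dir, "sparse.bed"))
  backend_add_track(be, "signal", "dense", file.path(dir, "dense.bedgraph"))
  backend_add_track(be, "hic", "interaction", file.path(dir, "interactions.bedpe"))
  be
}

query_delta <- function(be, expr) {
  before <- ledger_snapshot(be)
  force(expr)
  after <- ledger_snapshot(be)
  list(records = after$records_sent - before$records_sent,
       bases = after$bases_summarized - before$bases_summarized,
       requests = after$requests - before$requests,
       log = after$log[seq(before$requests + 1, length.out = after$requests -
                             before$requests), , drop = FALSE])
}

test_that("an identical repeated query transfers nothing", {
  be <- engine_fixture()
  ses <- cache_session(be)
  v <- viewport("chrI", 1000, 2000, 100)
  d1 <- query_delta(be, session_query(ses, c("peaks", "signal", "hic"), v))
  expect_gt(d1$requests, 0)
  d2 <- query_delta(be, session_query(ses, c("peaks", "signal", "hic"), v))
  expect_equal(d2$records, 0)
  expect_equal(d2$bases, 0)
  expect_equal(ses$query_counter, 2L)
})

test_that("a half-view shift fetches only the uncovered half", {
  be <- engine_fixture()
  ses <- cache_session(be)
  v1 <- viewport("chrI", 1000, 2000, 100)
  d1 <- query_delta(be, session_query(ses, "peaks", v1))
  expect_equal(unique(d1$log$start), 1000)  # first query: full viewport
  expect_equal(unique(d1$log$end), 2000)
  v2 <- viewport("chrI", 1500, 2500, 100)
  d2 <- query_delta(be, session_query(ses, "peaks", v2))
  expect_equal(nrow(d2$log), 1L)
  expect_equal(c(d2$log$start, d2$log$end), c(2000, 2500))
})

test_that("payloads match the brute-force oracle across random traces", {
  be <- engine_fixture()
  steps <- gen_trace(7, be$chroms, c("peaks", "signal", "hic"), n_steps = 40,
                     pixel_width = 80, interaction_tracks = "hic")
  res <- audit_trace(be, steps)
  expect_true(res$ok)
  expect_equal(res$n_steps, 40L)
  expect_gte(res$worst_balance, 0.292)
})

test_that("data untouched for the eviction window die exactly on time", {
  be <- engine_fixture()
  ses <- cache_session(be)
  a <- viewport("chrI", 0, 400, 50)
  b <- viewport("chrI", 4000, 4400, 50)
  session_query(ses, c("peaks", "signal"), a)
  oak_a <- ses$tracks$peaks$trees$chrI
  # nine further disjoint queries: region a survives (life 10 -> 1)
  for (i in 1:9) session_query(ses, c("peaks", "signal"), b)
  expect_true(oakpine:::iset_covers(oak_a$loaded, 0, 400))
  # the tenth untouched tick evicts it
  session_query(ses, c("peaks", "signal"), b)
  expect_false(oakpine:::iset_covers(oak_a$loaded, 0, 400))
  pine_a <- ses$tracks$signal$trees$chrI
  d_a <- pine_depth(5000, 400, 50)
  nodes <- oakpine:::pine_nodes_at_depth(pine_a, d_a, a$region)
  expect_true(all(vapply(nodes, `[[`, logical(1), "placeholder")) ||
                length(nodes) == 0L)
  # a re-query refetches and serves correct answers again
  d <- query_delta(be, p <- session_query(ses, c("peaks", "signal"), a))
  expect_gt(d$requests, 0)
  want <- oracle_query(be, c("peaks", "signal"), a)
  expect_equal(sort(p$tracks$peaks$records$id),
               sort(want$tracks$peaks$records$id))
  expect_equal(p$tracks$signal$profile$mean, want$tracks$signal$profile$mean)
})

test_that("touching a node resets its remaining life span", {
  be <- engine_fixture()
  ses <- cache_session(be)
  a <- viewport("chrI", 0, 400, 50)
  b <- viewport("chrI", 4000, 4400, 50)
  session_query(ses, "peaks", a)
  for (i in 1:5) session_query(ses, "peaks", b)
  session_query(ses, "peaks", a)  # reset at life 4
  for (i in 1:9) session_query(ses, "peaks", b)
  oak_a <- ses$tracks$peaks$trees$chrI
  expect_true(oakpine:::iset_covers(oak_a$loaded, 0, 400))
  session_query(ses, "peaks", b)
  expect_false(oakpine:::iset_covers(oak_a$loaded, 0, 400))
})

test_that("trees on other chromosomes are frozen, not aged", {
  be <- engine_fixture()
  ses <- cache_session(be)
  a <- viewport("chrI", 0, 400, 50)
  session_query(ses, "peaks", a)
  for (i in 1:15) session_query(ses, "peaks", viewport("chrII", 0, 400, 50))
  oak_a <- ses$tracks$peaks$trees$chrI
  expect_true(oakpine:::iset_covers(oak_a$loaded, 0, 400))
})

test_that("the transfer report reconciles per-query and cumulative totals", {
  be <- engine_fixture()
  ses <- cache_session(be)
  rep0 <- transfer_report(ses)
  expect_equal(nrow(rep0), 0L)
  v <- viewport("chrI", 1000, 2000, 100)
  session_query(ses, c("peaks", "signal"), v)
  session_query(ses, c("peaks", "signal"), v)
  rep <- transfer_report(ses)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$records_sent[2], 0)
  expect_equal(rep$bases_summarized[2], 0)
  expect_equal(rep$cum_records_sent, cumsum(rep$records_sent))
  expect_equal(rep$cum_bases_summarized, cumsum(rep$bases_summarized))
  snap <- ledger_snapshot(be)
  expect_equal(sum(rep$requests), snap$requests)
})

test_that("double-layer queries cache interactions by either anchor", {
  be <- engine_fixture()
  ses <- cache_session(be)
  top <- viewport("chrI", 0, 2000, 100)
  bottom <- viewport("chrII", 0, 5000, 100)
  p <- session_query(ses, "hic", top, bottom)
  want <- oracle_query(be, "hic", top, bottom)
  expect_equal(sort(p$tracks$hic$records$id), sort(want$tracks$hic$records$id))
  d <- query_delta(be, session_query(ses, "hic", top, bottom))
  expect_equal(d$records, 0)
})
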