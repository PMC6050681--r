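# Internal fringe accessor used to check structural invariants.
oak_fringe <- function(tree) tree$fringe

expect_fringe_partition <- function(tree) {
  fr <- oak_fringe(tree)
  expect_equal(fr$left[1], 0)
  expect_equal(fr$right[length(fr$right)], tree$chrom_len)
  if (length(fr$left) > 1L) {
    expect_equal(fr$left[-1], fr$right[-length(fr$right)])
  }
}

test_that("building an Oak keys unique starts and placeholders the rest", {
  ci <- toy_chroms(chr1 = 1000)
  recs <- read_toy_bed("chr1", c(10, 15, 35), c(20, 40, 50), chroms = ci)
  tree <- oak_build(recs, gi("chr1", 0, 100), ci)
  fr <- oak_fringe(tree)
  expect_fringe_partition(tree)
  # data keys: [0,10) [10,15) [15,35) [35,100); placeholder: [100,1000)
  expect_equal(fr$left[!fr$ph], c(0, 10, 15, 35))
  expect_equal(fr$left[fr$ph], 100)
  expect_equal(fr$right[fr$ph], 1000)
  loaded <- oak_loaded(tree)
  expect_length(loaded, 1L)
  expect_equal(c(loaded[[1]]$start, loaded[[1]]$end), c(0, 100))
})

test_that("an empty build is placeholder-covered but loaded", {
  ci <- toy_chroms(chr1 = 1000)
  recs <- read_toy_bed("chr1", integer(0), integer(0), name = character(0))
  tree <- oak_build(recs, gi("chr1", 0, 100), ci)
  expect_fringe_partition(tree)
  expect_equal(nrow(oak_retrieve(tree, gi("chr1", 0, 100))), 0L)
  loaded <- oak_loaded(tree)
  expect_equal(c(loaded[[1]]$start, loaded[[1]]$end), c(0, 100))
})

test_that("span lists hold records crossing a key's left boundary", {
  ci <- toy_chroms(chr1 = 1000)
  recs <- read_toy_bed("chr1", c(5, 30, 60), c(95, 45, 70), chroms = ci)
  tree <- oak_build(recs, gi("chr1", 0, 100), ci)
  fr <- oak_fringe(tree)
  long <- which(tree$records$start == 5)
  # start list membership at its own key only
  k5 <- which(fr$left == 5)
  expect_true(long %in% fr$start_idx[[k5]])
  for (k in seq_along(fr$left)) {
    if (fr$ph[k]) next
    in_span <- long %in% fr$span_idx[[k]]
    should <- fr$left[k] > 5 && fr$left[k] < 95
    expect_identical(in_span, should,
                     info = sprintf("key left=%g", fr$left[k]))
  }
})

test_that("updates extend coverage without re-inserting held records", {
  ci <- toy_chroms(chr1 = 1000)
  recs1 <- read_toy_bed("chr1", c(10, 80), c(30, 120), name = c("a", "b"))
  tree <- oak_build(recs1, gi("chr1", 0, 100), ci)
  ids_before <- tree$records$id
  # the record spanning 100 comes back from the backend for (100,200)
  recs2 <- read_toy_bed("chr1", c(80, 150), c(120, 160), name = c("b", "c"))
  oak_update(tree, gi("chr1", 100, 200), recs2)
  loaded <- oak_loaded(tree)
  expect_length(loaded, 1L)
  expect_equal(c(loaded[[1]]$start, loaded[[1]]$end), c(0, 200))
  expect_true(all(ids_before %in% tree$records$id))
  expect_equal(tree$duplicates, 1L)  # "b" deduplicated by identity
  expect_equal(nrow(tree$records), 3L)
  expect_fringe_partition(tree)
})

test_that("updating with a covered region and no records is a no-op", {
  ci <- toy_chroms(chr1 = 1000)
  recs <- read_toy_bed("chr1", c(10, 35), c(20, 50))
  tree <- oak_build(recs, gi("chr1", 0, 100), ci)
  before <- oak_dump(tree)
  oak_update(tree, gi("chr1", 20, 80),
             read_toy_bed("chr1", integer(0), integer(0), name = character(0)))
  expect_identical(oak_dump(tree), before)
})

test_that("interleaved updates coalesce the loaded set", {
  ci <- toy_chroms(chr1 = 1000)
  none <- read_toy_bed("chr1", integer(0), integer(0), name = character(0))
  tree <- oak_build(none, gi("chr1", 0, 50), ci)
  oak_update(tree, gi("chr1", 100, 150), none)
  oak_update(tree, gi("chr1", 50, 100), none)
  loaded <- oak_loaded(tree)
  expect_length(loaded, 1L)
  expect_equal(c(loaded[[1]]$start, loaded[[1]]$end), c(0, 150))
})

test_that("retrieval returns each overlapping record exactly once, sorted", {
  ci <- toy_chroms(chr1 = 1000)
  recs <- read_toy_bed("chr1", c(10, 15, 35, 20, 25, 30), c(20, 40, 50, 95, 28, 33),
                       chroms = ci)
  tree <- oak_build(recs, gi("chr1", 0, 100), ci)
  got <- oak_retrieve(tree, gi("chr1", 12, 38))
  want <- bf_overlapping(tree$records, "chr1", 12, 38)
  expect_equal(got$id, want$id)
  expect_false(any(duplicated(got$id)))
  # record (20,95) spans keys at 25, 30, 35: still returned once
  expect_equal(sum(got$start == 20), 1L)
  expect_equal(nrow(oak_retrieve(tree, gi("chr1", 0, 5))), 0L)
  expect_error(oak_retrieve(tree, gi("chr1", 50, 150)), "not fully loaded")
})

test_that("random build/update sequences agree with brute-force retrieval", {
  set.seed(31)
  ci <- toy_chroms(chrA = 1000)
  for (seq_i in 1:500) {
    n <- sample(3:25, 1)
    start <- sample.int(950, n, replace = TRUE)
    len <- sample.int(120, n, replace = TRUE)
    all_recs <- read_toy_bed("chrA", start, pmin(start + len, 1000))
    regions <- replicate(sample(2:4, 1), {
      s <- sample.int(990, 1); c(s, s + sample.int(1000 - s, 1))
    }, simplify = FALSE)
    fetchf <- function(iv) bf_overlapping(all_recs, "chrA", iv[1], iv[2])
    tree <- oak_build(fetchf(regions[[1]]),
                      gi("chrA", regions[[1]][1], regions[[1]][2]), ci)
    for (iv in regions[-1]) {
      oak_update(tree, gi("chrA", iv[1], iv[2]), fetchf(iv))
    }
    expect_fringe_partition(tree)
    # retrieve over each loaded region and compare to a direct scan
    for (lv in oak_loaded(tree)) {
      got <- oak_retrieve(tree, lv)
      want <- bf_overlapping(all_recs, "chrA", lv$start, lv$end)
      expect_equal(sort(got$id), sort(unique(want$id)),
                   info = sprintf("sequence %d", seq_i))
    }
    bal <- check_weight_balance(tree)
    expect_true(bal$balanced)
  }
})

test_that("trees are weight balanced and logarithmically shallow", {
  set.seed(41)
  ci <- toy_chroms(chrB = 100000)
  start <- sample.int(99000, 1000)
  recs <- read_toy_bed("chrB", start, start + sample.int(500, 1000, TRUE))
  tree <- oak_build(recs, gi("chrB", 0, 100000), ci)
  bal <- check_weight_balance(tree)
  expect_true(bal$balanced)
  expect_gte(bal$worst_ratio, tree$alpha)
  nl <- length(oak_fringe(tree)$left)
  expect_lte(oakpine:::oak_tree_depth(tree), ceiling(log2(nl)) + 2)

  # degenerate linear chain: the checker must reject it
  sub <- recs[seq_len(200), , drop = FALSE]
  chain <- oak_build(sub, gi("chrB", 0, 100000), ci, balance = FALSE)
  expect_false(check_weight_balance(chain)$balanced)

  single <- oak_build(read_toy_bed("chrB", 5, 10), gi("chrB", 0, 100000), ci)
  expect_true(check_weight_balance(single)$balanced)
})
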