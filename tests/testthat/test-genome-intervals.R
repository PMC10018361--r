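# Interval algebra: merge / intersect / subtract / extend / windows / UpSet

test_that("merge combines overlapping and book-ended intervals", {
  expect_equal(nrow(merge_intervals(interval_set())), 0L)

  x <- interval_set("chr1", c(10, 15, 40), c(20, 30, 50))
  m <- merge_intervals(x)
  expect_same_regions(m, data.frame(chrom = "chr1", start = c(10, 40),
                                    end = c(30, 50)))
  expect_true(attr(m, "merged"))

  # book-ended join on by default, off on request
  be <- interval_set("chr1", c(10, 20), c(20, 30))
  expect_equal(nrow(merge_intervals(be)), 1L)
  expect_equal(nrow(merge_intervals(be, book_ended = FALSE)), 2L)
})

test_that("merge is idempotent, order-invariant and conserves covered bases", {
  set.seed(42)
  lens <- c(chrA = 5000, chrB = 3000)
  for (rep in 1:10) {
    x <- random_iset(lens, 25)
    m <- merge_intervals(x)
    expect_identical(coords_df(merge_intervals(m)), coords_df(m))
    shuffled <- x[sample.int(nrow(x)), ]
    expect_identical(coords_df(merge_intervals(interval_set(
      shuffled$chrom, shuffled$start, shuffled$end))), coords_df(m))
    expect_equal(sum(m$end - m$start),
                 sum(sapply(oracle_mask(x, lens), sum)))
  }
})

test_that("invalid intervals are rejected naming the record", {
  expect_error(interval_set("chr1", 20, 20), "chr1:20-20")
  expect_error(interval_set("chr1", 30, 20), "invalid interval")
  expect_error(interval_set("chr1", -1, 5), "invalid interval")
})

test_that("intersect modes agree with hand-worked examples", {
  a <- interval_set("chr1", 10, 20)
  b <- interval_set("chr1", 15, 30)
  expect_equal(intersect_intervals(a, b, "bp"), 5)
  expect_equal(intersect_intervals(a, b, "count"), 1)
  expect_same_regions(intersect_intervals(a, b, "regions"),
                      data.frame(chrom = "chr1", start = 15, end = 20))

  disj <- interval_set("chr2", 0, 10)
  expect_equal(intersect_intervals(a, disj, "bp"), 0)
  expect_equal(intersect_intervals(a, disj, "count"), 0)
  expect_equal(nrow(intersect_intervals(a, disj, "regions")), 0L)

  # self-intersection returns the merged footprint
  x <- interval_set("chr1", c(0, 5, 100), c(10, 20, 150))
  expect_equal(intersect_intervals(x, x, "bp"), total_bp(x))
})

test_that("count mode counts each query record at most once", {
  a <- interval_set("chr1", 0, 100)        # one record, many b overlaps
  b <- interval_set("chr1", c(10, 30, 50), c(20, 40, 60))
  expect_equal(intersect_intervals(a, b, "count"), 1)
})

test_that("subtract supports per-base clipping and whole-record dropping", {
  a <- interval_set("chr1", 10, 30)
  b <- interval_set("chr1", 15, 20)
  expect_same_regions(subtract_intervals(a, b, "per-base"),
                      data.frame(chrom = "chr1", start = c(10, 20),
                                 end = c(15, 30)))
  expect_equal(nrow(subtract_intervals(a, b, "any-overlap")), 0L)

  x <- interval_set("chr1", c(0, 5), c(10, 20))
  expect_identical(coords_df(subtract_intervals(x, interval_set(), "per-base")),
                   coords_df(merge_intervals(x)))
  expect_equal(nrow(subtract_intervals(x, x, "per-base")), 0L)
})

test_that("extend_clamped widens symmetrically and clamps at edges", {
  gl <- genome_layout("chr1", 1e6)
  e <- extend_clamped(interval_set("chr1", 1000, 1001), 133, gl)
  expect_equal(c(e$start, e$end), c(867, 1134))
  expect_equal(e$end - e$start, 267)

  e0 <- extend_clamped(interval_set("chr1", 50, 51), 0, gl)
  expect_equal(c(e0$start, e0$end), c(50, 51))

  ec <- extend_clamped(interval_set("chr1", 50, 51), 133, gl)
  expect_equal(c(ec$start, ec$end), c(0, 184))

  er <- extend_clamped(interval_set("chr1", 999990, 999991), 133, gl)
  expect_equal(er$end, 1e6)

  expect_error(extend_clamped(interval_set("chrX", 0, 10), 5, gl),
               "unknown chromosome")
  expect_error(extend_clamped(interval_set("chr1", 0, 10), -1, gl),
               "non-negative")
})

test_that("make_windows tiles each chromosome exactly", {
  gl <- genome_layout("chr1", 120)
  w <- make_windows(gl, 50)
  expect_equal(w$start, c(0, 50, 100))
  expect_equal(w$end, c(50, 100, 120))

  expect_equal(nrow(make_windows(genome_layout("c", 30), 50)), 1L)
  expect_error(make_windows(gl, 0), "window_size")

  set.seed(7)
  for (rep in 1:5) {
    gl <- genome_layout(paste0("chr", 1:3), sample(1000:9999, 3))
    W <- sample(50:500, 1)
    w <- make_windows(gl, W)
    expect_equal(sum(w$end - w$start), genome_size(gl))
    expect_true(all(w$end - w$start <= W))
    expect_true(all(tapply(w$end - w$start < W, w$chrom, sum) <= 1))
  }
})

test_that("binarize_windows flags any >= 1 bp overlap", {
  gl <- genome_layout("chr1", 5000)
  grid <- make_windows(gl, 1000)
  m <- binarize_windows(grid, list(p = interval_set("chr1", 900, 1100)))
  expect_identical(unname(m[, "p"]), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  m0 <- binarize_windows(grid, list(p = interval_set()))
  expect_false(any(m0))
})

test_that("membership counts form an exclusive partition", {
  gl <- genome_layout("chr1", 10000)
  grid <- make_windows(gl, 1000)
  set.seed(3)
  tracks <- list(a = random_iset(c(chr1 = 10000), 4),
                 b = random_iset(c(chr1 = 10000), 4),
                 c = random_iset(c(chr1 = 10000), 4))
  m <- binarize_windows(grid, tracks)
  mc <- membership_counts(m)

  # exhaustive enumeration over windows
  lab <- apply(m, 1, function(r) paste(names(tracks)[r], collapse = "&"))
  expected <- table(lab[nzchar(lab)])
  expect_equal(sum(mc$combinations), sum(rowSums(m) > 0))
  for (nm in names(expected)) {
    expect_equal(unname(mc$combinations[nm]), unname(as.integer(expected[nm])))
  }
  # pairwise shared fractions
  for (k in 1:3) {
    f <- m[, k]
    if (any(f)) {
      expect_equal(mc$per_track$frac_shared[k],
                   sum(f & rowSums(m[, -k, drop = FALSE]) > 0) / sum(f))
    }
  }

  one <- membership_counts(m[, 1, drop = FALSE])
  expect_length(one$combinations, if (any(m[, 1])) 1L else 0L)
  expect_equal(sum(one$combinations), sum(m[, 1]))
})

test_that("all region operations agree with the per-base oracle", {
  set.seed(101)
  lens <- c(chr1 = 4000, chr2 = 2500)
  gl <- genome_layout(names(lens), lens)
  for (case in 1:40) {
    a <- random_iset(lens, sample(1:15, 1))
    b <- random_iset(lens, sample(1:15, 1))
    expect_same_regions(merge_intervals(a), oracle_merge(a, lens))
    expect_same_regions(intersect_intervals(a, b, "regions"),
                        oracle_intersect_regions(a, b, lens))
    expect_equal(intersect_intervals(a, b, "bp"), oracle_intersect_bp(a, b, lens))
    expect_equal(intersect_intervals(a, b, "bp"), intersect_intervals(b, a, "bp"))
    expect_equal(intersect_intervals(a, b, "count"), oracle_count_hits(a, b, lens))
    expect_same_regions(subtract_intervals(a, b, "per-base"),
                        oracle_subtract_perbase(a, b, lens))
    expect_equal(coords_df(subtract_intervals(a, b, "any-overlap")),
                 {
                   d <- oracle_subtract_drop(a, b, lens)
                   d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
                   rownames(d) <- NULL
                   d
                 })
    # subtraction then intersection with the subtrahend is empty
    expect_equal(intersect_intervals(subtract_intervals(a, b, "per-base"), b, "bp"), 0)
    # clamped extension stays inside the genome
    f <- sample(0:300, 1)
    e <- extend_clamped(a, f, gl)
    expect_true(all(e$start >= 0 & e$end <= lens[e$chrom]))
    inner <- a$start >= f & a$end + f <= lens[a$chrom]
    expect_true(all((e$end - e$start)[inner] == (a$end - a$start)[inner] + 2 * f))
  }
})
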