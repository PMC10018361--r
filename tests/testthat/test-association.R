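# Permutation association engine: randomization, Z / empirical p, fold change

test_that("randomization keeps chromosome and width and is seed-deterministic", {
  gl <- genome_layout(c("chr1", "chr2"), c(10000, 4000))
  set.seed(5)
  x <- random_iset(c(chr1 = 10000, chr2 = 4000), 30)
  r1 <- randomize_intervals(x, gl, seed = 11)
  r2 <- randomize_intervals(x, gl, seed = 11)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(sort(paste(r1$chrom, r1$end - r1$start)),
                   sort(paste(x$chrom, x$end - x$start)))
  expect_true(all(r1$start >= 0 & r1$end <= chrom_length(gl, r1$chrom)))

  # an interval as wide as its chromosome has a single placement
  full <- interval_set("chr2", 0, 4000)
  expect_equal(randomize_intervals(full, gl, seed = 1)$start, 0)
  # wider than the chromosome is impossible
  expect_error(randomize_intervals(interval_set("chr2", 0, 4001),
                                   genome_layout("chr2", 4000)),
               "wider than")
})

test_that("randomized starts are uniform over the feasible range", {
  gl <- genome_layout("c", 10)
  x <- interval_set("c", 0, 3)           # width 3 -> starts 0..7
  set.seed(99)
  starts <- replicate(10000, randomize_intervals(x, gl)$start)
  tab <- table(factor(starts, levels = 0:7))
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("permutation test flags planted enrichment and reports the p floor", {
  gl <- genome_layout("chr1", 1e6)
  feat <- interval_set("chr1", seq(0, 980000, 20000), seq(0, 980000, 20000) + 1000)
  sb <- simulate_breaks(gl, 400, features = feat, rho = 0.6, proximity = 0,
                        seed = 21)
  r <- permutation_test(sb$breaks, feat, gl, n_perm = 500, seed = 22)
  expect_gt(r$z, 3)
  expect_equal(r$p_value, 1 / 501)
  expect_identical(r$direction, "greater")
  expect_equal(r$z, (r$observed - r$null_mean) / r$null_sd)
})

test_that("identical seeds reproduce the full result", {
  gl <- genome_layout(c("a", "b"), c(50000, 30000))
  set.seed(4)
  q <- random_iset(c(a = 50000, b = 30000), 40)
  ref <- random_iset(c(a = 50000, b = 30000), 40)
  r1 <- permutation_test(q, ref, gl, n_perm = 200, seed = 123)
  r2 <- permutation_test(q, ref, gl, n_perm = 200, seed = 123)
  expect_identical(r1[names(r1) != "null_values"], r2[names(r2) != "null_values"])
  expect_identical(r1$null_values, r2$null_values)
})

test_that("a constant permutation null raises a degenerate-null error", {
  gl <- genome_layout("chr1", 1000)
  q <- interval_set("chr1", 10, 20)
  none <- interval_set()                  # no reference anywhere -> null all 0
  expect_error(permutation_test(q, none, gl, n_perm = 50, seed = 1),
               class = "dsbtools_degenerate_null")
})

test_that("depletion yields direction 'less' and negative Z", {
  gl <- genome_layout("chr1", 100000)
  # reference covers the first 90%; query sits in the uncovered tail
  ref <- interval_set("chr1", 0, 90000)
  q <- interval_set("chr1", seq(91000, 99000, 1000), seq(91000, 99000, 1000) + 100)
  r <- permutation_test(q, ref, gl, n_perm = 300, seed = 17)
  expect_lt(r$z, 0)
  expect_identical(r$direction, "less")
  expect_lte(r$p_value, 0.05)
})

test_that("adding reference intervals never decreases the observed count", {
  set.seed(31)
  lens <- c(chr1 = 20000)
  q <- random_iset(lens, 25)
  ref <- random_iset(lens, 10)
  extra <- random_iset(lens, 10)
  grown <- interval_set(c(ref$chrom, extra$chrom), c(ref$start, extra$start),
                        c(ref$end, extra$end))
  expect_gte(intersect_intervals(q, grown, "count"),
             intersect_intervals(q, ref, "count"))
})

test_that("null means match the exact placement-enumeration expectation", {
  set.seed(61)
  for (case in 1:4) {
    len <- sample(300:1000, 1)
    gl <- genome_layout("c", len)
    q <- random_iset(c(c = len), sample(3:6, 1))
    q$end <- pmin(q$end, q$start + 50)    # keep widths modest
    ref <- random_iset(c(c = len), 3)
    for (stat in c("count", "bp")) {
      exact <- exact_expected_stat(q, ref, len, stat)
      r <- tryCatch(
        permutation_test(q, ref, gl, n_perm = 2000, statistic = stat, seed = case),
        error = function(e) NULL)        # degenerate nulls can occur on toys
      if (is.null(r)) next
      se <- r$null_sd / sqrt(r$n_permutations)
      expect_lt(abs(r$null_mean - exact), 3 * se + 1e-9)
    }
  }
})

test_that("fold change is exactly 1 for a genome-covering annotation", {
  gl <- genome_layout("chr1", 50000)
  seg <- interval_set("chr1", c(100, 5000), c(300, 5400))
  ann <- interval_set("chr1", 0, 50000)
  expect_warning(fc <- fold_change_test(seg, ann, gl, n_samples = 50, seed = 2),
                 NA)
  expect_equal(fc$fold, 1.0)
  expect_equal(fc$observed, fc$expected)
})

test_that("sampled expected overlap matches exhaustive enumeration on a toy", {
  gl <- genome_layout("c", 1000)
  seg <- interval_set("c", 100, 110)      # width 10 -> 991 placements
  ann <- interval_set("c", 500, 600)      # one 100 bp annotation
  exact <- exact_expected_stat(as.data.frame(seg), as.data.frame(ann), 1000, "bp")
  fc <- fold_change_test(seg, ann, gl, n_samples = 20000, seed = 5)
  # Monte-Carlo error of the mean overlap
  expect_lt(abs(fc$expected - exact), 0.5)
  expect_equal(fc$observed, 0)
})

test_that("empty expected overlap yields the infinite-fold sentinel", {
  # a tiny annotation on a huge chromosome: a small sample of random
  # placements sees no overlap at all while the observed overlap is full
  gl <- genome_layout("a", 1e7)
  seg <- interval_set("a", 0, 10)
  ann <- interval_set("a", 0, 10)
  expect_warning(fc <- fold_change_test(seg, ann, gl, n_samples = 20, seed = 3),
                 "Inf")
  expect_identical(fc$fold, Inf)
  expect_equal(fc$observed, 10)
})

test_that("stratified association partitions the query", {
  gl <- genome_layout("chr1", 200000)
  set.seed(77)
  q <- random_iset(c(chr1 = 200000), 50)
  ref <- random_iset(c(chr1 = 200000), 40)

  whole <- interval_set("chr1", 0, 200000)
  st <- stratified_association(q, ref, whole, gl, n_perm = 100, seed = 9)
  expect_false(st$computed[["non_overlap"]])
  expect_null(st$non_overlap)
  expect_equal(st$n_overlap + st$n_non_overlap, nrow(q))
  full <- permutation_test(q, ref, gl, n_perm = 100, seed = 9)
  expect_equal(st$overlap$z, full$z)

  strat <- interval_set("chr1", 0, 100000)
  st2 <- stratified_association(q, ref, strat, gl, n_perm = 100, seed = 9)
  expect_equal(st2$n_overlap + st2$n_non_overlap, nrow(q))
})

test_that("enrichment planted only outside the stratifier shows up in the non-overlap stratum", {
  gl <- genome_layout("chr1", 2e6)
  # features live in the second half; stratifier is the first half
  feat <- interval_set("chr1", seq(1e6, 1.96e6, 2e4), seq(1e6, 1.96e6, 2e4) + 1000)
  strat <- interval_set("chr1", 0, 1e6)
  sb_in <- simulate_breaks(gl, 150, seed = 41)            # background everywhere
  sb_out <- simulate_breaks(gl, 150, features = feat, rho = 0.8, proximity = 0,
                            seed = 42)
  q <- interval_set(c(sb_in$breaks$chrom, sb_out$breaks$chrom),
                    c(sb_in$breaks$start, sb_out$breaks$start),
                    c(sb_in$breaks$end, sb_out$breaks$end))
  st <- stratified_association(q, feat, strat, gl, n_perm = 300, seed = 43)
  expect_true(all(st$computed))
  expect_gt(st$non_overlap$z, st$overlap$z)
})
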