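test_that("kw_test matches hand computation and stats::kruskal.test", {
  r <- kw_test(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$H, 12 / 42 * 13.5, tolerance = 1e-12)  # 3.857...
  r0 <- kw_test(list(c(2, 2, 2), c(2, 2, 2)))
  expect_equal(r0$H, 0)
  expect_equal(r0$p, 1)
  expect_error(kw_test(list(1:5)), "2 groups")

  set.seed(17)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    g <- lapply(seq_len(k), function(j) {
      # coarse values force ties
      sample(1:6, sample(3:12, 1), replace = TRUE)
    })
    ours <- kw_test(g)
    ref <- kruskal.test(unlist(g), factor(rep(seq_len(k), lengths(g))))
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-group KW agrees with the normal-approximation Wilcoxon", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(25)
    b <- rnorm(25, 0.4)
    kw <- kw_test(list(a, b))
    w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_lt(abs(kw$p - w$p.value), 0.01)
  }
})

test_that("row-wise KW equals the scalar implementation", {
  set.seed(29)
  X <- matrix(sample(0:20, 40 * 15, replace = TRUE), 40, 15,
              dimnames = list(sprintf("a%02d", 1:40),
                              sprintf("s%02d", 1:15)))
  res <- antigenome:::kw_test_rows(X, colnames(X)[1:8], colnames(X)[9:15])
  for (i in c(1, 7, 40)) {
    ref <- kw_test(list(X[i, 1:8], X[i, 9:15]))
    expect_equal(res$H[i], ref$H, tolerance = 1e-10)
    expect_equal(res$p[i], ref$p, tolerance = 1e-10)
  }
})

test_that("bh_fdr equals the brute-force step-up on random vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 6)), rep(1, 6))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(37)
  worst <- 0
  for (i in 1:10000) {
    p <- runif(sample(1:10, 1))^sample(1:3, 1)
    worst <- max(worst, max(abs(bh_fdr(p) - oracle_bh(p))))
  }
  expect_lt(worst, 1e-12)
  # q >= p and q matches stats::p.adjust
  p <- runif(200)
  expect_true(all(bh_fdr(p) >= p))
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
})

test_that("differential_selection applies the documented cascade gates", {
  set.seed(41)
  n <- 60
  samples <- c(sprintf("c%02d", 1:20), sprintf("h%02d", 1:15))
  norm <- matrix(rnorm(n * 35, 5), n, 35,
                 dimnames = list(sprintf("P%02d", 1:n), samples))
  calls <- matrix(0L, n, 35, dimnames = dimnames(norm))
  # antigens 1-5: strong case signal with high prevalence
  norm[1:5, 1:20] <- norm[1:5, 1:20] + 4
  calls[1:5, 1:12] <- 1L
  # antigen 6: signal but below the 1% prevalence filter (no calls)
  norm[6, 1:20] <- norm[6, 1:20] + 4
  res <- differential_selection(norm, calls, samples[1:20], samples[21:35],
                                min_prevalence = 0.05)
  expect_true(all(res$significant[1:5]))
  expect_false(res$tested[6])  # pre-filtered despite signal
  expect_true(all(res$direction[1:5] == "case-enriched"))
  expect_true(all(res$q[res$tested] >= res$p[res$tested]))
  expect_equal(attr(res, "n_tested"), sum(res$tested))

  # empty pre-filter result warns and returns an empty table
  expect_warning(
    res0 <- differential_selection(norm, calls * 0L, samples[1:20],
                                   samples[21:35]),
    "prevalence pre-filter")
  expect_equal(sum(res0$significant), 0)
})

test_that("a 541 + 322 significant table totals 863 flagged antigens", {
  # bookkeeping example on the headline discovery split
  n <- 4357
  res <- data.frame(
    antigen = sprintf("A%04d", 1:n),
    significant = rep(c(TRUE, FALSE), c(863, n - 863)),
    direction = c(rep("case-enriched", 541), rep("control-enriched", 322),
                  rep(NA, n - 863)))
  case_n <- sum(res$significant & res$direction == "case-enriched",
                na.rm = TRUE)
  ctrl_n <- sum(res$significant & res$direction == "control-enriched",
                na.rm = TRUE)
  expect_equal(case_n, 541)
  expect_equal(ctrl_n, 322)
  expect_equal(sum(res$significant), 863)
})

test_that("split-set partitions follow exact set algebra", {
  set1 <- sprintf("A%04d", 1:541)
  set2 <- c(sprintf("A%04d", 1:335), sprintf("B%04d", 1:270))
  part <- subgroup_overlap(list(set1 = set1, set2 = set2))
  expect_equal(overlap_unique(part, "set1"), 206)
  expect_equal(overlap_unique(part, "set2"), 270)
  expect_equal(unname(part$counts["set1&set2"]), 335)

  same <- subgroup_overlap(list(a = set1, b = set1))
  expect_equal(overlap_unique(same, "a"), 0)
  expect_equal(overlap_unique(same, "b"), 0)
  disjoint <- subgroup_overlap(list(a = "x", b = "y"))
  expect_equal(unname(disjoint$counts[c("a", "b")]), c(1, 1))
  expect_true(is.na(disjoint$counts["a&b"]))
})

test_that("split_set_reproducibility stratifies, seeds, and intersects", {
  set.seed(47)
  n <- 80
  case <- sprintf("c%02d", 1:24)
  hc <- sprintf("h%02d", 1:16)
  strata <- rep(c("g1", "g2", "g3"), each = 8)
  norm <- matrix(rnorm(n * 40, 5), n, 40,
                 dimnames = list(sprintf("P%02d", 1:n), c(case, hc)))
  calls <- matrix(0L, n, 40, dimnames = dimnames(norm))
  norm[1:6, 1:24] <- norm[1:6, 1:24] + 5
  calls[1:6, 1:24] <- 1L
  sp <- split_set_reproducibility(norm, calls, case, strata, hc, seed = 7,
                                  min_prevalence = 0.05)
  # stratified halves: 4 per stratum per set
  expect_equal(as.integer(table(sp$assignment)), c(12L, 12L))
  for (s in unique(strata)) {
    expect_equal(sum(sp$assignment[strata == s] == 1), 4)
  }
  # identical reruns reproduce the assignment; different seeds move it
  sp2 <- split_set_reproducibility(norm, calls, case, strata, hc, seed = 7,
                                   min_prevalence = 0.05)
  expect_identical(sp$assignment, sp2$assignment)
  expect_setequal(sp$reproducible, intersect(sp$hits1, sp$hits2))
  expect_setequal(sp$partition$shared, sp$reproducible)
  expect_error(split_set_reproducibility(norm, calls, case[1:3],
                                         c("a", "a", "b"), hc),
               "2 case samples per stratum")
})

test_that("prevalence_filter is monotone and respects bounds", {
  set.seed(53)
  prev <- setNames(runif(100), sprintf("P%03d", 1:100))
  hits <- names(prev)[1:60]
  expect_identical(prevalence_filter(hits, prev, 0), hits)
  expect_length(prevalence_filter(hits, prev, 1.01), 0)
  f10 <- prevalence_filter(hits, prev, 0.1)
  f30 <- prevalence_filter(hits, prev, 0.3)
  expect_true(all(f30 %in% f10))
})

test_that("subgroup_overlap equals brute-force enumeration", {
  pools <- sprintf("P%03d", 1:120)
  # the published subgroup bookkeeping: 262/217 sharing 171 -> 91 and 46
  a <- sprintf("A%03d", 1:262)
  b <- c(sprintf("A%03d", 1:171), sprintf("B%03d", 1:46))
  part <- subgroup_overlap(list("RNF-A" = a, "RNF-NA" = b))
  expect_equal(overlap_unique(part, "RNF-A"), 91)
  expect_equal(overlap_unique(part, "RNF-NA"), 46)

  four <- subgroup_overlap(list(a = a, b = a, c = a, d = a))
  expect_equal(unname(four$counts["a&b&c&d"]), 262)
  expect_equal(sum(four$counts), four$union_size)

  set.seed(59)
  sets <- lapply(1:4, function(i) sample(pools, sample(10:80, 1)))
  names(sets) <- c("w", "x", "y", "z")
  part4 <- subgroup_overlap(sets)
  # oracle: enumerate membership of every id
  for (id in sample(unique(unlist(sets)), 25)) {
    sig <- paste(names(sets)[vapply(sets, function(s) id %in% s,
                                    logical(1))], collapse = "&")
    expect_true(id %in% part4$regions[[sig]])
  }
  expect_equal(sum(part4$counts), length(unique(unlist(sets))))
  expect_error(subgroup_overlap(c(sets, list(v = pools))), "2 and 4")
})

test_that("rank_bias_diagnostic ranks by representation", {
  rep_counts <- setNames(100:1, sprintf("P%03d", 1:100))
  top10 <- names(rep_counts)[1:10]
  rb <- rank_bias_diagnostic(top10, rep_counts)
  expect_equal(rb$median, 5.5)
  expect_equal(rb$range, c(1, 10))
  expect_equal(rank_bias_diagnostic(top10[3], rep_counts)$median, 3)
  expect_error(rank_bias_diagnostic("NOPE", rep_counts), "absent")

  set.seed(61)
  N <- 10000
  repr <- setNames(rlnorm(N, 0, 2), sprintf("G%05d", 1:N))
  k <- 500
  hits <- sample(names(repr), k)
  rb2 <- rank_bias_diagnostic(hits, repr)
  se_med <- N / (2 * sqrt(k))
  expect_lt(abs(rb2$median - (N + 1) / 2), 3 * se_med)
})

test_that("signed-rank engine matches stats::wilcox.test", {
  set.seed(67)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- x + rnorm(15, 0.3)
    ours <- antigenome:::signed_rank_test(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = FALSE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("longitudinal_paired finds planted rises and per-donor R2", {
  set.seed(71)
  n_ant <- 150
  donors <- sprintf("D%02d", 1:30)
  mk <- function(tp, shift_rows = NULL) {
    m <- matrix(rnorm(n_ant * 30, 6, 0.5), n_ant, 30,
                dimnames = list(sprintf("P%03d", 1:n_ant),
                                paste0(donors, "_T", tp)))
    if (!is.null(shift_rows)) m[shift_rows, ] <- m[shift_rows, ] + 2
    m
  }
  norm <- cbind(mk(0), mk(24, shift_rows = 1:10))
  meta <- data.frame(
    sample_id = colnames(norm),
    donor_id = rep(donors, 2),
    timepoint = rep(c(0, 24), each = 30),
    is_control = FALSE)
  lp <- longitudinal_paired(norm, meta)
  sig <- lp$tests$antigen[lp$tests$q < 0.2]
  expect_true(all(sprintf("P%03d", 1:10) %in% sig))
  expect_lt(length(setdiff(sig, sprintf("P%03d", 1:10))), 8)

  # identical profiles at both visits: no signal, per-donor R2 = 1
  m0 <- mk(0)
  norm2 <- cbind(m0, `colnames<-`(m0, paste0(donors, "_T24")))
  lp2 <- longitudinal_paired(norm2, meta)
  expect_equal(sum(lp2$tests$q < 0.2, na.rm = TRUE), 0)
  expect_equal(lp2$r2$r2, rep(1, 30))

  # unpaired donors are excluded with a warning
  expect_warning(longitudinal_paired(norm[, -1], meta[-1, ]), "unpaired")
})
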