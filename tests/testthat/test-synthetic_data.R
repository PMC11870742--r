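test_that("generated proteomes satisfy their invariants", {
  pr <- generate_proteome(30, seed = 4)
  # coding sequences translate exactly to the amino-acid sequences
  # (independent oracle: Biostrings translation)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(pr$proteins$nt)))
  expect_identical(unname(aa), pr$proteins$aa)
  expect_true(all(pr$expression >= 0))
  expect_true(all(rowSums(pr$expression > 0) >= 1))
  expect_identical(anyDuplicated(pr$proteins$protein_id), 0L)
})

test_that("overlap configuration is honoured", {
  member_all <- matrix(TRUE, 4, 4)
  pr <- generate_proteome(4, overlap_config = list(membership = member_all),
                          seed = 1)
  cx <- library_complexity(data.frame(
    protein_id = rep(pr$proteins$protein_id, 4),
    source = rep(pr$sources, each = 4)))
  four_way <- cx$venn[lengths(strsplit(names(cx$venn), "&")) == 4]
  expect_equal(unname(four_way), 4L)
  expect_length(cx$venn, 1L)

  member <- matrix(TRUE, 6, 4)
  member[1:2, 2:4] <- FALSE  # two proteins exclusive to source 1
  pr2 <- generate_proteome(6, overlap_config = list(membership = member),
                           seed = 1)
  expressed <- pr2$expression > 0
  rows <- do.call(rbind, lapply(seq_len(4), function(j) {
    data.frame(protein_id = rownames(expressed)[expressed[, j]],
               source = pr2$sources[j])
  }))
  expect_equal(unname(library_complexity(rows)$unique_contribution[
    pr2$sources[1]]), 2L)
})

test_that("fixed seeds give byte-identical FASTA output", {
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  for (d in c(d1, d2)) {
    pr <- generate_proteome(20, seed = 9)
    pool <- build_fragment_library(pr, candidates_per_source = 100, seed = 10)
    co <- generate_serum_cohort(pr, design = list(groups = c(HC = 3),
                                                  timepoints = 0), seed = 11)
    cnt <- simulate_cohort_screens(pool, co, depth = 1000, seed = 12)
    emit_dataset(pool, co, cnt, d, proteome = pr)
  }
  for (f in c("proteins.fasta", "fragments.fasta", "fragment_counts.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("ORF funnel pass rate matches the analytic per-candidate probability", {
  pr <- generate_proteome(60, seed = 15)
  pool <- build_fragment_library(pr, candidates_per_source = 4000,
                                 orientation_flip_p = 0.05, seed = 16)
  funnel <- attr(pool, "funnel")
  n <- sum(vapply(funnel, `[[`, numeric(1), "candidates"))
  passed <- sum(vapply(funnel, `[[`, numeric(1), "passed"))
  ncod <- unlist(lapply(funnel, `[[`, "candidate_codons"))
  p_exp <- mean(expected_candidate_pass_prob(ncod, flip_p = 0.05))
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(passed / n - p_exp), 3 * se)
})

test_that("orientation handling at the funnel boundaries", {
  pr <- generate_proteome(10, seed = 2)
  # flip_p = 0 and frame 0 would always pass; with sampled frames the
  # forward fraction is still the full candidate set
  pool <- build_fragment_library(pr, candidates_per_source = 200,
                                 orientation_flip_p = 0, seed = 3)
  expect_true(all(pool$orientation == "+"))
  # all-reversed candidates can never pass the read-through screen
  expect_error(
    build_fragment_library(pr, candidates_per_source = 50,
                           orientation_flip_p = 1, seed = 3),
    "no candidate fragment passed")
  expect_error(build_fragment_library(pr, min_insert = 10),
               "min_insert")
})

test_that("cohort design arithmetic and planted prevalence", {
  pr <- generate_proteome(100, seed = 31)
  co <- generate_serum_cohort(
    pr, design = list(groups = c("HC" = 43, "PBO-A" = 27, "PBO-NA" = 21,
                                 "RNF-A" = 27, "RNF-NA" = 27),
                      timepoints = c(0, 6, 24)),
    disease_pool = list(n_antigens = 10, prevalence = 0.3,
                        hc_prevalence = 0.02, fold = 10),
    seed = 32)
  donor_rows <- co$manifest[!co$manifest$is_control, ]
  expect_equal(nrow(donor_rows), 306 + 129)  # 102 x 3 + 43 x 3
  expect_equal(sum(donor_rows$group != "HC"), 306)

  # realized planted prevalence within 3 binomial SE of pi per group
  truth <- co$truth
  donors <- unique(donor_rows[, c("donor_id", "group")])
  for (g in c("PBO-A", "RNF-NA")) {
    ids <- donors$donor_id[donors$group == g]
    inc <- mean(unlist(lapply(truth$donor_planted[ids], length)) /
                  length(truth$planted_antigens))
    se <- sqrt(0.3 * 0.7 / (length(ids) * length(truth$planted_antigens)))
    expect_lt(abs(inc - 0.3), 3 * se)
  }
  hc_ids <- donors$donor_id[donors$group == "HC"]
  inc_hc <- mean(unlist(lapply(truth$donor_planted[hc_ids], length)) /
                   length(truth$planted_antigens))
  expect_lt(inc_hc, 0.1)
})

test_that("degenerate disease-pool configurations", {
  pr <- generate_proteome(50, seed = 41)
  co0 <- generate_serum_cohort(
    pr, design = list(groups = c(HC = 4, "PBO-A" = 4), timepoints = 0),
    disease_pool = list(n_antigens = 5, prevalence = 0, fold = 10),
    seed = 42)
  expect_equal(sum(lengths(co0$truth$donor_planted)), 0)

  co1 <- generate_serum_cohort(
    pr, design = list(groups = c(HC = 2, "PBO-A" = 5), timepoints = 0),
    disease_pool = list(n_antigens = 5, prevalence = 1,
                        hc_prevalence = 0, fold = 10),
    seed = 43)
  planted <- co1$truth$planted_antigens
  donors <- names(co1$profiles)
  for (d in donors[grepl("PBOA", donors)]) {
    expect_setequal(co1$profiles[[d]]$planted, planted)
  }
  expect_error(
    generate_serum_cohort(pr, design = list(groups = c(HC = 2)),
                          disease_pool = list(prevalence = 0.5), seed = 1),
    "disease_pool empty")
})

test_that("donor targets persist across time points", {
  pr <- generate_proteome(80, seed = 51)
  co <- generate_serum_cohort(
    pr, design = list(groups = c("PBO-A" = 4), timepoints = c(0, 6, 24)),
    disease_pool = list(n_antigens = 6, prevalence = 1, fold = 10),
    drift = 0, seed = 52)
  p <- co$profiles[[1]]
  t0 <- p$targets_by_time[["0"]]
  t24 <- p$targets_by_time[["24"]]
  expect_identical(t0$protein_id, t24$protein_id)
  lens <- setNames(pr$proteins$length_aa, pr$proteins$protein_id)
  expect_true(all(t0$aa_end <= lens[t0$protein_id]))
  expect_true(all(t0$aa_start >= 0))
  expect_true(all(is.finite(t0$reactivity) & t0$reactivity >= 0))
})

test_that("simulate_screen matches its selection model", {
  pr <- generate_proteome(40, seed = 61)
  pool <- build_fragment_library(pr, candidates_per_source = 600, seed = 62)

  # background-only profile: proportions converge to input abundance
  co <- generate_serum_cohort(pr, design = list(groups = c(HC = 1),
                                                timepoints = 0),
                              background = list(targets_per_donor = 0),
                              seed = 63)
  prof <- co$profiles[[1]]
  counts <- simulate_screen(pool, prof, depth = 1e6,
                            concentration = Inf, seed = 64)
  expect_equal(sum(counts), 1e6)
  p <- pool$input_abundance
  keep <- p > 1e-4
  se <- sqrt(p[keep] * (1 - p[keep]) / 1e6)
  expect_true(all(abs(counts[keep] / 1e6 - p[keep]) < 4 * se + 1e-12))

  # a single dominant target captures the majority of reads
  target_prot <- pool$protein_id[which.max(pool$input_abundance)]
  lens <- setNames(pr$proteins$length_aa, pr$proteins$protein_id)
  prof2 <- prof
  prof2$targets_by_time[["0"]] <- data.frame(
    protein_id = target_prot, aa_start = 0L,
    aa_end = lens[[target_prot]], reactivity = 1e4)
  counts2 <- simulate_screen(pool, prof2, depth = 1e5,
                             concentration = Inf, seed = 65)
  on_target <- sum(counts2[pool$protein_id == target_prot])
  expect_gt(on_target / 1e5, 0.5)

  # depth 0 gives an all-zero vector; unknown target protein errors
  expect_equal(sum(simulate_screen(pool, prof, depth = 0)), 0)
  prof3 <- prof
  prof3$targets_by_time[["0"]] <- data.frame(
    protein_id = "UNKNOWN", aa_start = 0L, aa_end = 10L, reactivity = 1)
  expect_error(simulate_screen(pool, prof3, depth = 10),
               "consistency error")
})

test_that("datasets round-trip losslessly through emit/read", {
  sc <- small_screen(seed = 71, n_proteins = 60,
                     groups = c(HC = 3, "PBO-A" = 3), pool_size = 4,
                     depth = 2e4)
  d <- file.path(tempdir(), "roundtrip")
  emit_dataset(sc$pool, sc$cohort, sc$frag_counts, d,
               proteome = sc$proteome)
  back <- read_dataset(d)
  expect_identical(back$antigen_counts, sc$antigen_counts)
  expect_identical(back$fragment_counts, sc$frag_counts)
  expect_setequal(back$truth$planted_antigens,
                  sc$cohort$truth$planted_antigens)
  expect_identical(back$manifest$sample_id, sc$meta$sample_id)
  expect_identical(setNames(back$pool$seq, back$pool$fragment_id),
                   setNames(sc$pool$seq, sc$pool$fragment_id))
  unlink(d, recursive = TRUE)
})
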