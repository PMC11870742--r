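# Differential-selection cascade: Kruskal-Wallis + Benjamini-Hochberg,
# split-set reproducibility, overlap algebra, rank-bias diagnostic, and
# longitudinal paired testing.

#' Kruskal-Wallis rank-sum test (tie-corrected)
#'
#' Midranks with the standard tie correction; p value from the
#' chi-squared approximation with `k - 1` degrees of freedom.
#'
#' @param groups list of >= 2 numeric vectors.
#' @return list with `H` (statistic), `p`, `df`.
#' @export
#' @examples
#' kw_test(list(c(1, 2, 3), c(4, 5, 6)))$H  # 3.857...
kw_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need >= 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("need total n >= 3")
  g <- rep.int(seq_along(groups), sizes)
  r <- rank(x)
  rg <- vapply(split(r, g), sum, numeric(1))
  H <- 12 / (n * (n + 1)) * sum(rg^2 / sizes) - 3 * (n + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  H <- if (C > 0) H / C else 0
  df <- length(groups) - 1L
  list(H = H, p = pchisq(H, df, lower.tail = FALSE), df = df)
}

# Row-wise two-group Kruskal-Wallis over a matrix; returns H, p and the
# difference in mean ranks (case - control) for direction calls.
kw_test_rows <- function(X, case_cols, control_cols) {
  M <- X[, c(case_cols, control_cols), drop = FALSE]
  n1 <- length(case_cols)
  n2 <- length(control_cols)
  n <- n1 + n2
  ranks <- t(apply(M, 1L, rank))
  r1 <- rowSums(ranks[, seq_len(n1), drop = FALSE])
  r2 <- rowSums(ranks[, n1 + seq_len(n2), drop = FALSE])
  H <- 12 / (n * (n + 1)) * (r1^2 / n1 + r2^2 / n2) - 3 * (n + 1)
  tiesum <- apply(M, 1L, function(x) {
    t <- tabulate(match(x, unique(x)))
    sum(t^3 - t)
  })
  C <- 1 - tiesum / (n^3 - n)
  H <- ifelse(C > 0, H / C, 0)
  data.frame(H = H,
             p = pchisq(H, 1L, lower.tail = FALSE),
             rank_diff = r1 / n1 - r2 / n2,
             row.names = rownames(M))
}

#' Benjamini-Hochberg step-up q values
#'
#' @param p vector of p values in `[0, 1]` (NA allowed; propagated).
#' @return q values; monotone non-decreasing in sorted p, capped at 1.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp)
    qq <- pmin(1, rev(cummin(rev(pp[o] * m / seq_len(m)))))
    q[ok][o] <- qq
    q[ok] <- q[ok]
  }
  q
}

#' Differential selection of antigens between a case and a control group
#'
#' The cascade's per-comparison core: antigens are pre-filtered to those
#' selected (binary calls) by at least `min_prevalence` of the case
#' samples; the surviving antigens are tested case vs control with the
#' Kruskal-Wallis test on normalised values; BH correction is applied
#' within the tested set only; direction is assigned by higher mean rank
#' (ties conservatively to control-enriched).
#'
#' @param norm antigen x sample matrix of normalised values
#'   (log2 CPM + 1 by convention; the rank test is invariant to monotone
#'   transforms).
#' @param calls binary antigen x sample matrix (same columns available).
#' @param case_samples,control_samples column names of the two arms.
#' @param min_prevalence case-prevalence pre-filter (default 0.01).
#' @param p_threshold,q_threshold significance gates (defaults 0.05, 0.2).
#' @return data frame, one row per antigen: `antigen`, `tested`, `H`,
#'   `p`, `q`, `direction`, `prev_case`, `prev_control`, `significant`.
#'   Attribute `n_tested` records the BH universe size.
#' @export
differential_selection <- function(norm, calls, case_samples,
                                   control_samples,
                                   min_prevalence = 0.01,
                                   p_threshold = 0.05,
                                   q_threshold = 0.2) {
  if (length(case_samples) == 0L || length(control_samples) == 0L) {
    stop("both groups must be non-empty")
  }
  prev_case <- rowMeans(calls[, case_samples, drop = FALSE])
  prev_control <- rowMeans(calls[, control_samples, drop = FALSE])
  tested <- prev_case >= min_prevalence
  res <- data.frame(antigen = rownames(norm), tested = tested,
                    H = NA_real_, p = NA_real_, q = NA_real_,
                    direction = NA_character_,
                    prev_case = prev_case, prev_control = prev_control,
                    significant = FALSE, stringsAsFactors = FALSE)
  rownames(res) <- res$antigen
  if (!any(tested)) {
    warning("no antigen survives the prevalence pre-filter")
    attr(res, "n_tested") <- 0L
    return(res)
  }
  kw <- kw_test_rows(norm[tested, , drop = FALSE], case_samples,
                     control_samples)
  res$H[tested] <- kw$H
  res$p[tested] <- kw$p
  res$q[tested] <- bh_fdr(kw$p)
  res$direction[tested] <- ifelse(kw$rank_diff > 0, "case-enriched",
                                  "control-enriched")
  res$significant <- res$tested & !is.na(res$p) &
    res$p < p_threshold & res$q < q_threshold
  attr(res, "n_tested") <- sum(tested)
  res
}

#' Split-set reproducibility of case-enriched antigens
#'
#' Case samples are split into two stratified random halves (strata =
#' subgroup labels; an odd stratum's extra sample goes to the half that
#' is currently smaller, ties to set 1).  [differential_selection()] is
#' run per half against the same controls; the case-direction significant
#' hits of the two halves are intersected, and only shared hits are
#' "reproducible".
#'
#' @param norm,calls as in [differential_selection()].
#' @param case_samples case sample ids.
#' @param strata subgroup label per case sample (same order).
#' @param control_samples control sample ids (shared by both halves).
#' @param seed split seed.
#' @param ... thresholds forwarded to [differential_selection()].
#' @return list with `assignment` (1/2 per case sample), `res1`, `res2`,
#'   `hits1`, `hits2`, `partition` (unique1 / shared / unique2 id sets),
#'   `reproducible` (= shared).
#' @export
split_set_reproducibility <- function(norm, calls, case_samples, strata,
                                      control_samples, seed = 1L, ...) {
  stopifnot(length(strata) == length(case_samples))
  if (any(table(strata) < 2L)) stop("need >= 2 case samples per stratum")
  assignment <- with_seed(seed, {
    a <- integer(length(case_samples))
    n1 <- 0L
    n2 <- 0L
    for (s in unique(strata)) {
      idx <- sample(which(strata == s))
      h <- length(idx) %/% 2L
      set1 <- idx[seq_len(h)]
      extra <- if (length(idx) %% 2L == 1L) idx[h + 1L] else integer(0)
      a[set1] <- 1L
      a[setdiff(idx, set1)] <- 2L
      if (length(extra)) {
        a[extra] <- if (n1 <= n2) 1L else 2L
      }
      n1 <- n1 + sum(a[idx] == 1L)
      n2 <- n2 + sum(a[idx] == 2L)
    }
    a
  })
  res1 <- differential_selection(norm, calls, case_samples[assignment == 1L],
                                 control_samples, ...)
  res2 <- differential_selection(norm, calls, case_samples[assignment == 2L],
                                 control_samples, ...)
  hit <- function(r) r$antigen[r$significant &
                                 r$direction == "case-enriched"]
  hits1 <- hit(res1)
  hits2 <- hit(res2)
  shared <- intersect(hits1, hits2)
  list(assignment = assignment, res1 = res1, res2 = res2,
       hits1 = hits1, hits2 = hits2,
       partition = list(unique1 = setdiff(hits1, hits2),
                        shared = shared,
                        unique2 = setdiff(hits2, hits1)),
       reproducible = shared)
}

#' Filter hits by case-group prevalence
#'
#' @param hits antigen ids.
#' @param prevalence named prevalence vector (fractions).
#' @param min_prevalence retention threshold (>=).
#' @return the retained ids (monotone in the threshold).
#' @export
prevalence_filter <- function(hits, prevalence, min_prevalence) {
  hits[prevalence[hits] >= min_prevalence]
}

#' Venn partition of 2-4 named antigen sets
#'
#' @param sets named list of 2 to 4 character vectors.
#' @return an `OverlapPartition`: list with `regions` (named list of
#'   exclusive-region id vectors, names like `"A&B"`), `counts`,
#'   `union_size`, `set_names`.
#' @export
#' @examples
#' subgroup_overlap(list(A = c("x", "y"), B = c("y", "z")))$counts
subgroup_overlap <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    stop("between 2 and 4 sets are supported")
  }
  nm <- names(sets) %||% LETTERS[seq_along(sets)]
  if (is.null(names(sets))) names(sets) <- nm
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  member <- matrix(member, nrow = length(ids), dimnames = list(ids, nm))
  sig <- apply(member, 1L, function(row) paste(nm[row], collapse = "&"))
  regions <- split(ids, sig)
  counts <- vapply(regions, length, integer(1))
  structure(list(regions = regions, counts = counts,
                 union_size = length(ids), set_names = nm),
            class = "OverlapPartition")
}

#' @export
print.OverlapPartition <- function(x, ...) {
  cat("OverlapPartition over", length(x$set_names), "sets; union",
      x$union_size, "\n")
  print(x$counts)
  invisible(x)
}

#' Count of ids exclusive to one set of an overlap partition
#'
#' @param partition an `OverlapPartition`.
#' @param set set name.
#' @return integer count (0 when the region is empty).
#' @export
overlap_unique <- function(partition, set) {
  n <- partition$counts[set]
  if (is.na(n)) 0L else unname(n)
}

#' Input-library representation rank diagnostic for a hit set
#'
#' Antigens are ranked by their input-library representation (rank 1 =
#' most represented; average ranks on ties); the median and range of the
#' hit set's ranks indicate whether selection merely tracked library
#' abundance.
#'
#' @param hits antigen ids.
#' @param representation named per-antigen representation (e.g. input
#'   CPM or fragment counts) covering all antigens.
#' @return list with `median`, `range`, `ranks`.
#' @export
rank_bias_diagnostic <- function(hits, representation) {
  if (!all(hits %in% names(representation))) {
    stop("hit(s) absent from the representation ranking")
  }
  rk <- rank(-representation, ties.method = "average")
  hr <- rk[hits]
  list(median = median(hr), range = range(hr), ranks = hr)
}

# Wilcoxon signed-rank test (zero differences excluded, midranks, normal
# approximation with tie correction).
signed_rank_test <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(W = NA_real_, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0) return(list(W = W, p = 1))
  z <- (W - mu) / sqrt(sig2)
  list(W = W, p = 2 * pnorm(-abs(z)))
}

#' Longitudinal paired analysis across time points
#'
#' For each ordered pair of time points: a per-antigen Wilcoxon
#' signed-rank test on paired donor values (donors missing either visit
#' are excluded with a warning; zero differences dropped), BH-corrected
#' within the pair; and a per-donor between-visit scatter R-squared table
#' (as [replicate_r2()]).
#'
#' @param norm antigen x sample matrix of normalised (log-scale) values.
#' @param meta metadata for the columns (`sample_id`, `donor_id`,
#'   `timepoint`, `is_control`).
#' @param timepoints which time points to compare (default: all observed,
#'   consecutive pairs plus first-vs-last).
#' @param min_pairs minimum paired donors per comparison (default 5).
#' @return list with `tests` (antigen x pair long data frame with `W`,
#'   `p`, `q`) and `r2` (donor x pair data frame).
#' @export
longitudinal_paired <- function(norm, meta, timepoints = NULL,
                                min_pairs = 5L) {
  meta <- meta[!meta$is_control & meta$sample_id %in% colnames(norm), ]
  tps <- sort(unique(timepoints %||% meta$timepoint))
  if (length(tps) < 2L) stop("need >= 2 time points")
  pairs <- t(utils::combn(tps, 2L))
  tests <- list()
  r2 <- list()
  for (k in seq_len(nrow(pairs))) {
    t1 <- pairs[k, 1L]
    t2 <- pairs[k, 2L]
    m1 <- meta[meta$timepoint == t1, ]
    m2 <- meta[meta$timepoint == t2, ]
    donors <- intersect(m1$donor_id, m2$donor_id)
    dropped <- setdiff(union(m1$donor_id, m2$donor_id), donors)
    if (length(dropped)) {
      warning(length(dropped), " unpaired donor(s) excluded for ",
              t1, " vs ", t2)
    }
    if (length(donors) < min_pairs) {
      stop("fewer than ", min_pairs, " paired donors for ", t1, " vs ", t2)
    }
    s1 <- m1$sample_id[match(donors, m1$donor_id)]
    s2 <- m2$sample_id[match(donors, m2$donor_id)]
    X1 <- norm[, s1, drop = FALSE]
    X2 <- norm[, s2, drop = FALSE]
    wt <- lapply(seq_len(nrow(norm)), function(i) {
      signed_rank_test(X1[i, ], X2[i, ])
    })
    p <- vapply(wt, `[[`, numeric(1), "p")
    tests[[k]] <- data.frame(
      antigen = rownames(norm), pair = paste0(t1, "-", t2),
      W = vapply(wt, `[[`, numeric(1), "W"), p = p, q = bh_fdr(p),
      stringsAsFactors = FALSE)
    r2[[k]] <- data.frame(
      donor_id = donors, pair = paste0(t1, "-", t2),
      r2 = vapply(seq_along(donors), function(j) {
        replicate_r2(X1[, j], X2[, j])
      }, numeric(1)), stringsAsFactors = FALSE)
  }
  list(tests = do.call(rbind, tests), r2 = do.call(rbind, r2))
}
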