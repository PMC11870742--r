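# Protein sequence property calculators (antigenicity scales) and
# GSEA-style enrichment of a hit set within a property-ranked proteome.

aa_values <- function(seq, table, skip_nonstandard = FALSE) {
  chars <- strsplit(seq, "")[[1]]
  v <- table[chars]
  if (anyNA(v)) {
    if (skip_nonstandard) {
      chars <- chars[!is.na(v)]
      v <- v[!is.na(v)]
    } else {
      pos <- which(is.na(v))[1]
      stop("nonstandard residue '", chars[pos], "' at position ", pos)
    }
  }
  unname(v)
}

# centred moving average with truncated windows at the edges
moving_average <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Sliding-window profile of a residue scale
#'
#' Per-residue values are the centred arithmetic mean of the scale over a
#' window (truncated at the sequence edges); the protein score is the
#' mean of the per-residue values.
#'
#' @param seq amino-acid sequence (20 standard residues).
#' @param scale a scale name for [aa_scale()] or a named numeric vector.
#' @param window odd window size, `<=` sequence length (default 7, the
#'   common epitope-scale convention).
#' @param skip_nonstandard drop nonstandard residues instead of erroring.
#' @return list with `per_residue` and `protein_score`.
#' @export
#' @examples
#' scale_profile("III", "kyte_doolittle", window = 1)$protein_score  # 4.5
scale_profile <- function(seq, scale, window = 7L,
                          skip_nonstandard = FALSE) {
  if (is.character(scale) && length(scale) == 1L) scale <- aa_scale(scale)
  if (window %% 2L != 1L) stop("window must be odd")
  v <- aa_values(seq, scale, skip_nonstandard)
  if (window > length(v)) stop("window exceeds sequence length")
  per <- moving_average(v, window)
  list(per_residue = per, protein_score = mean(per))
}

#' Emini surface accessibility
#'
#' For every hexapeptide window the score is the product of the six
#' residues' fractional surface probabilities normalised by
#' `norm^-6` (norm = 0.37, the average surface fraction), so a window of
#' average residues scores 1.  The protein score is the mean over
#' windows.
#'
#' @param seq amino-acid sequence, length >= 6.
#' @param table named surface-fraction vector (default
#'   `aa_scale("emini_surface")`).
#' @param norm normalising constant (default 0.37).
#' @return list with `per_window` and `protein_score`.
#' @export
emini_accessibility <- function(seq, table = aa_scale("emini_surface"),
                                norm = 0.37) {
  v <- aa_values(seq, table)
  n <- length(v)
  if (n < 6L) stop("sequence shorter than the hexapeptide window")
  lg <- c(0, cumsum(log(v)))
  starts <- seq_len(n - 5L)
  s <- exp(lg[starts + 6L] - lg[starts]) * norm^-6
  list(per_window = s, protein_score = mean(s))
}

#' Chou-Fasman secondary-structure fractions
#'
#' Fraction of residues assigned to beta turns and beta sheets under the
#' classical propensity rules.  A tetrapeptide starting at `i` nucleates
#' a turn iff the positional bend-frequency product
#' `f(i) f(i+1) f(i+2) f(i+3)` exceeds 7.5e-5, the mean turn propensity
#' over the tetrad exceeds 1.0, and it exceeds both the mean helix and
#' mean sheet propensities; its four residues are assigned turn.  A
#' sheet window (length `sheet_window`) assigns its residues sheet iff
#' its mean sheet propensity is at least 1.05 and exceeds the mean helix
#' propensity.
#'
#' @param seq amino-acid sequence, length >= 4.
#' @param p_t_threshold bend-probability product threshold.
#' @param sheet_window sheet nucleation window (default 5).
#' @return list with `turn_fraction`, `sheet_fraction`, logical
#'   per-residue assignment vectors.
#' @export
chou_fasman_fractions <- function(seq, p_t_threshold = 7.5e-5,
                                  sheet_window = 5L) {
  pa <- aa_values(seq, aa_scale("cf_helix"))
  pb <- aa_values(seq, aa_scale("cf_sheet"))
  pt <- aa_values(seq, aa_scale("cf_turn"))
  f1 <- aa_values(seq, aa_scale("cf_turn_f1"))
  f2 <- aa_values(seq, aa_scale("cf_turn_f2"))
  f3 <- aa_values(seq, aa_scale("cf_turn_f3"))
  f4 <- aa_values(seq, aa_scale("cf_turn_f4"))
  n <- length(pa)
  if (n < 4L) stop("sequence shorter than a tetrapeptide")
  turn <- logical(n)
  idx <- seq_len(n - 3L)
  p_t <- f1[idx] * f2[idx + 1L] * f3[idx + 2L] * f4[idx + 3L]
  mean4 <- function(v) (v[idx] + v[idx + 1L] + v[idx + 2L] + v[idx + 3L]) / 4
  mt <- mean4(pt)
  ma <- mean4(pa)
  mb <- mean4(pb)
  nucleates <- p_t > p_t_threshold & mt > 1 & mt > ma & mt > mb
  if (any(nucleates)) {
    turn[unique(as.vector(outer(idx[nucleates], 0:3, "+")))] <- TRUE
  }
  sheet <- logical(n)
  if (n >= sheet_window) {
    widx <- seq_len(n - sheet_window + 1L)
    csb <- c(0, cumsum(pb))
    csa <- c(0, cumsum(pa))
    mb_w <- (csb[widx + sheet_window] - csb[widx]) / sheet_window
    ma_w <- (csa[widx + sheet_window] - csa[widx]) / sheet_window
    hit <- mb_w >= 1.05 & mb_w > ma_w
    if (any(hit)) {
      sheet[unique(as.vector(outer(widx[hit],
                                   0:(sheet_window - 1L), "+")))] <- TRUE
    }
  }
  list(turn_fraction = mean(turn), sheet_fraction = mean(sheet),
       turn = turn, sheet = sheet)
}

# net charge at a given pH (Henderson-Hasselbalch over termini and
# ionisable side chains)
peptide_charge <- function(composition, pH, pka) {
  pos <- pka[pka$charge == "positive", ]
  neg <- pka[pka$charge == "negative", ]
  count_of <- function(g) {
    if (g == "Nterm" || g == "Cterm") 1 else composition[g] %||% 0
  }
  total <- 0
  for (i in seq_len(nrow(pos))) {
    cnt <- count_of(pos$group[i])
    if (!is.na(cnt) && cnt > 0) {
      total <- total + cnt / (1 + 10^(pH - pos$pka[i]))
    }
  }
  for (i in seq_len(nrow(neg))) {
    cnt <- count_of(neg$group[i])
    if (!is.na(cnt) && cnt > 0) {
      total <- total - cnt / (1 + 10^(neg$pka[i] - pH))
    }
  }
  total
}

#' Isoelectric point by bisection
#'
#' Solves net charge(pH) = 0 by bisection on `(0, 14)` using
#' Henderson-Hasselbalch terms for the termini and the ionisable side
#' chains (D, E, C, Y, H, K, R) with the EMBOSS pKa set (see
#' [pka_set()]).  Converges to `|charge| < tol` within `max_iter`
#' iterations (charge is strictly decreasing in pH).
#'
#' @param seq amino-acid sequence (non-empty).
#' @param pka pKa table as returned by [pka_set()].
#' @param tol charge tolerance (default 1e-4).
#' @param max_iter bisection cap (default 60).
#' @return the pI.
#' @export
#' @examples
#' isoelectric_point("GG")  # 6.1 (midpoint of the terminal pKas)
isoelectric_point <- function(seq, pka = pka_set(), tol = 1e-4,
                              max_iter = 60L) {
  if (nchar(seq) == 0L) stop("empty sequence")
  chars <- strsplit(seq, "")[[1]]
  comp <- table(chars)
  comp <- setNames(as.numeric(comp), names(comp))
  lo <- 0
  hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    ch <- peptide_charge(comp, mid, pka)
    if (abs(ch) < tol) return(mid)
    if (ch > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Property table for a set of proteins
#'
#' Computes the package's antigenicity scales for every protein: mean
#' Chou-Fasman turn propensity profile (window 7), turn and sheet
#' fractions, Emini accessibility, Parker hydrophilicity (window 7),
#' Kyte-Doolittle GRAVY (plain mean), and isoelectric point.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @return data frame in long format: `protein_id`, `scale`, `score`.
#' @export
protein_property_table <- function(sequences) {
  rows <- lapply(names(sequences), function(id) {
    s <- sequences[[id]]
    cf <- chou_fasman_fractions(s)
    data.frame(
      protein_id = id,
      scale = c("chou_fasman_turn", "fraction_beta_turn",
                "fraction_beta_sheet", "emini_accessibility",
                "parker_hydrophilicity", "gravy_hydrophobicity",
                "isoelectric_point"),
      score = c(scale_profile(s, "cf_turn", 7L)$protein_score,
                cf$turn_fraction, cf$sheet_fraction,
                emini_accessibility(s)$protein_score,
                scale_profile(s, "parker", 7L)$protein_score,
                scale_profile(s, "kyte_doolittle", 1L)$protein_score,
                isoelectric_point(s)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' GSEA-style enrichment of a hit set in a ranked proteome
#'
#' Unweighted Kolmogorov-Smirnov running sum over the score-ranked
#' universe: hits increment by `1/|hits|`, non-hits decrement by
#' `1/(N - |hits|)`; the enrichment score ES is the signed extremum.
#' The null is built from random same-size hit sets; NES = ES divided by
#' the mean |null ES| of matching sign; the p value is two-sided with +1
#' smoothing.
#'
#' @param scores named score vector over the full universe (higher =
#'   stronger property).
#' @param hits hit ids (subset of `names(scores)`).
#' @param n_perm number of permutations (>= 100).
#' @param seed permutation seed.
#' @return an `EnrichmentResult` list: `es`, `nes`, `p`,
#'   `leading_edge`, `n_perm`, `seed`.
#' @export
gsea_enrichment <- function(scores, hits, n_perm = 1000L, seed = 1L) {
  if (length(hits) == 0L) stop("empty hit set")
  if (!all(hits %in% names(scores))) {
    stop("hit set must be a subset of the ranked universe")
  }
  if (n_perm < 100L) stop("n_perm must be >= 100")
  N <- length(scores)
  nh <- length(hits)
  ord <- order(scores, decreasing = TRUE)
  ranked_ids <- names(scores)[ord]
  is_hit <- ranked_ids %in% hits
  es_of <- function(hit_ind) {
    steps <- ifelse(hit_ind, 1 / nh, -1 / (N - nh))
    run <- cumsum(steps)
    run[which.max(abs(run))]
  }
  es <- es_of(is_hit)
  extremum_at <- which.max(abs(cumsum(ifelse(is_hit, 1 / nh,
                                             -1 / (N - nh)))))
  leading <- if (es >= 0) {
    ranked_ids[seq_len(extremum_at)][is_hit[seq_len(extremum_at)]]
  } else {
    ranked_ids[extremum_at:N][is_hit[extremum_at:N]]
  }
  null_es <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ind <- logical(N)
      ind[sample.int(N, nh)] <- TRUE
      es_of(ind)
    }, numeric(1))
  })
  same_sign <- null_es[sign(null_es) == sign(es)]
  denom <- if (length(same_sign)) mean(abs(same_sign)) else mean(abs(null_es))
  nes <- if (denom > 0) es / denom else 0
  p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
  structure(list(es = es, nes = nes, p = p, leading_edge = leading,
                 n_perm = n_perm, seed = seed),
            class = "EnrichmentResult")
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: ES %.3f, NES %.2f, p %.4g (%d perms)\n",
              x$es, x$nes, x$p, x$n_perm))
  invisible(x)
}
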