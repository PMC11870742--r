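# In-silico two-plasmid ORF screening and library QC.
#
# The cloning funnel is modelled after a sequential 2-plasmid system: the
# first vector requires translational read-through of the insert to confer
# antibiotic resistance, the second requires read-through for phage coat
# protein fusion.  Both contracts reduce to: forward orientation and no
# stop codon from the recorded cloning frame to the end of the insert.

split_codons <- function(seq, from = 1L) {
  n <- nchar(seq)
  if (n - from + 1L < 3L) return(character(0))
  starts <- seq.int(from, n - 2L, by = 3L)
  substring(seq, starts, starts + 2L)
}

check_acgt <- function(seq) {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0) {
    stop("non-ACGT character '", substring(seq, bad, bad),
         "' at position ", bad)
  }
  invisible(TRUE)
}

#' Screen a cloned insert for translational read-through
#'
#' Classifies a nucleotide insert under the two-plasmid read-through
#' contract: an insert passes iff it is in the forward orientation and
#' translating from its recorded frame offset to the end of the insert
#' encounters no stop codon (`TAA`, `TAG`, `TGA`).  Deterministic.
#'
#' @param seq nucleotide sequence over `{A,C,G,T}`, length >= 3.
#' @param orientation `"+"` (forward) or `"-"` (reverse).
#' @param frame cloning frame offset in `{0,1,2}`: translation starts at
#'   base `frame + 1` of the insert.
#' @return list with `pass` (logical) and `classification`, one of
#'   `"pass"`, `"wrong_orientation"`, `"stop_in_frame"`.
#' @export
#' @examples
#' screen_orf("ATGAAACTG")$classification         # "pass"
#' screen_orf("ATGTAACTG")$classification         # "stop_in_frame"
screen_orf <- function(seq, orientation = "+", frame = 0L) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 3L,
            frame %in% 0:2)
  check_acgt(seq)
  if (orientation == "-") {
    return(list(pass = FALSE, classification = "wrong_orientation"))
  }
  codons <- split_codons(seq, from = frame + 1L)
  if (any(codons %in% stop_codons)) {
    return(list(pass = FALSE, classification = "stop_in_frame"))
  }
  list(pass = TRUE, classification = "pass")
}

# Vectorised classification used by the library builder; same contract as
# screen_orf() but without per-sequence validation overhead.
screen_orf_many <- function(seqs, orientations, frames) {
  n <- length(seqs)
  cls <- character(n)
  rev <- orientations == "-"
  cls[rev] <- "wrong_orientation"
  idx <- which(!rev)
  for (i in idx) {
    codons <- split_codons(seqs[i], from = frames[i] + 1L)
    cls[i] <- if (any(codons %in% stop_codons)) "stop_in_frame" else "pass"
  }
  cls
}

#' Clone-validation statistics for a set of screened inserts
#'
#' Reproduces the Sanger-style validation readout of a cloning funnel.
#' Three fractions are reported with documented denominators (all = number
#' of inserts screened):
#' \describe{
#'   \item{orf_fraction}{inserts whose best forward frame translates at
#'     least `orf_min_fraction` of the insert length without a stop.}
#'   \item{inframe_fraction}{inserts that pass [screen_orf()] in their
#'     recorded cloning frame (forward and stop-free).}
#'   \item{orientation_fraction}{inserts in the forward orientation.}
#' }
#'
#' @param inserts data frame with columns `seq`, `orientation`, `frame`.
#' @param orf_min_fraction fraction of the insert length that must be
#'   translatable in the best forward frame to count as an ORF (default
#'   0.8; the underlying readout has no published denominator definition,
#'   so the threshold is exposed).
#' @return list of the three fractions plus `n`.
#' @export
clone_validation_stats <- function(inserts, orf_min_fraction = 0.8) {
  if (!is.data.frame(inserts) || nrow(inserts) == 0L) {
    stop("'inserts' must be a non-empty data frame")
  }
  n <- nrow(inserts)
  cls <- screen_orf_many(inserts$seq, inserts$orientation, inserts$frame)
  best_orf <- vapply(inserts$seq, function(s) {
    len <- nchar(s)
    best <- 0L
    for (f in 0:2) {
      codons <- split_codons(s, from = f + 1L)
      stop_at <- which(codons %in% stop_codons)
      ncod <- if (length(stop_at)) stop_at[1L] - 1L else length(codons)
      best <- max(best, 3L * ncod)
    }
    best / len
  }, numeric(1))
  list(
    orf_fraction = mean(best_orf >= orf_min_fraction),
    inframe_fraction = mean(cls == "pass"),
    orientation_fraction = mean(inserts$orientation == "+"),
    n = n,
    denominators = "all fractions are over the full set of screened inserts"
  )
}

#' Closed-form probability that a random insert is clonable in frame
#'
#' Under the null model that codons are uniform over the 64 triplets, the
#' probability that `n_codons` consecutive codons are stop-free is
#' `(61/64)^n_codons`.  Optional factors multiply in the probability of
#' correct orientation (1/2) and of landing in the correct frame (1/3),
#' giving the classical "1 in ~10^6 for a 100-aa fragment" order of
#' magnitude when all requirements are compounded over two sequential
#' cloning steps.
#'
#' @param n_codons number of codons (vectorised).
#' @param orientation if `TRUE`, multiply by 1/2.
#' @param frame if `TRUE`, multiply by 1/3.
#' @return probability vector.
#' @export
#' @examples
#' expected_inframe_probability(1)        # 61/64
#' expected_inframe_probability(100)      # ~8.19e-3
expected_inframe_probability <- function(n_codons, orientation = FALSE,
                                         frame = FALSE) {
  stopifnot(all(n_codons >= 1))
  p <- (61 / 64)^n_codons
  if (orientation) p <- p / 2
  if (frame) p <- p / 3
  p
}

#' Analytic pass probability for a simulated candidate fragment
#'
#' Matches the generative model of [build_fragment_library()]: a candidate
#' is forward with probability `1 - flip_p`; a forward candidate lands on
#' the codon grid of its source protein with probability 1/3 (then passes
#' with certainty, coding sequences being stop-free in frame), otherwise
#' it reads a shifted frame whose ~`n_codons - 1` triplets are
#' approximately uniform, passing with probability `(61/64)^(n_codons-1)`.
#' The shifted-frame term is an approximation (shifted triplets of sense
#' codons are not exactly uniform) but it is a small additive contribution.
#'
#' @param n_codons insert length in codons (vectorised).
#' @param flip_p orientation flip probability.
#' @return probability vector.
#' @export
expected_candidate_pass_prob <- function(n_codons, flip_p = 0) {
  (1 - flip_p) *
    (1 / 3 + (2 / 3) * expected_inframe_probability(pmax(n_codons - 1, 1)))
}

#' Library complexity: per-source protein counts and Venn partition
#'
#' @param map data frame with columns `protein_id` and `source`, one row
#'   per fragment (or per protein-source pair).
#' @return list with `per_source` (distinct protein counts),
#'   `venn` (named counts of every exclusive region, names like
#'   `"A&B"`), `union_size`, and `unique_contribution` per source.
#' @export
library_complexity <- function(map) {
  if (nrow(map) == 0L) stop("empty fragment->protein map")
  sets <- lapply(split(map$protein_id, map$source), unique)
  src <- names(sets)
  if (length(src) < 1L) stop("no sources in map")
  all_ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  member <- matrix(member, nrow = length(all_ids),
                   dimnames = list(all_ids, src))
  sig <- apply(member, 1L, function(row) paste(src[row], collapse = "&"))
  venn <- table(sig)
  venn <- setNames(as.integer(venn), names(venn))
  uniq <- vapply(src, function(s) sum(sig == s), integer(1))
  list(per_source = vapply(sets, length, integer(1)),
       venn = venn,
       union_size = length(all_ids),
       unique_contribution = uniq,
       membership = member)
}

#' Library QC summary
#'
#' Per-source insert-size statistics, fragments-per-protein summary, the
#' rank-abundance curve of fragment counts per protein (descending; plot
#' on a log10 axis), and - when present - the ORF-screen funnel statistics
#' recorded by [build_fragment_library()].
#'
#' @param pool a `FragmentPool`.
#' @return list with elements `insert_size`, `fragments_per_protein`,
#'   `rank_abundance`, `complexity`, `funnel`.
#' @export
library_qc_summary <- function(pool) {
  stopifnot(inherits(pool, "FragmentPool"))
  sizes <- nchar(pool$seq)
  by_src <- split(sizes, pool$source)
  insert_size <- lapply(by_src, function(x) {
    list(n = length(x), mean = mean(x), median = median(x), sd = sd(x))
  })
  fpp <- table(pool$protein_id)
  rank_ab <- sort(as.integer(fpp), decreasing = TRUE)
  list(
    insert_size = insert_size,
    fragments_per_protein = list(mean = mean(fpp),
                                 range = range(as.integer(fpp))),
    rank_abundance = rank_ab,
    complexity = library_complexity(pool[, c("protein_id", "source")]),
    funnel = attr(pool, "funnel")
  )
}

#' Fragment tiling and per-residue coverage of one protein
#'
#' Fragment nucleotide intervals (0-based half-open on the coding
#' sequence) are projected to amino-acid coordinates as the residues whose
#' codons are touched by the interval: `aa_start = floor(start/3)`,
#' `aa_end = ceiling(end/3)`.
#'
#' @param protein_id protein identifier.
#' @param pool a `FragmentPool`.
#' @param protein_length protein length in residues; taken from the pool
#'   attribute `protein_lengths` when omitted.
#' @return list with `intervals` (data frame fragment_id/aa_start/aa_end,
#'   0-based half-open) and `depth` (integer vector, one per residue).
#' @export
fragment_coverage <- function(protein_id, pool, protein_length = NULL) {
  stopifnot(inherits(pool, "FragmentPool"))
  if (is.null(protein_length)) {
    pl <- attr(pool, "protein_lengths")
    if (is.null(pl) || !protein_id %in% names(pl)) {
      stop("unknown protein '", protein_id, "'")
    }
    protein_length <- pl[[protein_id]]
  }
  rows <- pool[pool$protein_id == protein_id, , drop = FALSE]
  if (nrow(rows) == 0L && !protein_id %in% names(attr(pool, "protein_lengths") %||% character())) {
    stop("unknown protein '", protein_id, "'")
  }
  aa_start <- rows$start %/% 3L
  aa_end <- pmin((rows$end + 2L) %/% 3L, protein_length)
  depth <- integer(protein_length)
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      if (aa_end[i] > aa_start[i]) {
        idx <- (aa_start[i] + 1L):aa_end[i]
        depth[idx] <- depth[idx] + 1L
      }
    }
  }
  list(intervals = data.frame(fragment_id = rows$fragment_id,
                              aa_start = aa_start, aa_end = aa_end,
                              stringsAsFactors = FALSE),
       depth = depth)
}
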