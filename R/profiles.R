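# Count-matrix model: aggregation, normalisation, batch factors, binary
# selection calls, replicate QC.

#' Aggregate fragment counts to antigen (protein) level
#'
#' Antigen count = sum of its fragments' counts; column sums (total reads
#' per sample) are conserved.
#'
#' @param frag_counts fragment x sample integer matrix.
#' @param map a `FragmentPool` or data frame with `fragment_id` and
#'   `protein_id`.
#' @return antigen x sample integer matrix.
#' @export
aggregate_fragments_to_antigens <- function(frag_counts, map) {
  idx <- match(rownames(frag_counts), map$fragment_id)
  if (anyNA(idx)) {
    bad <- rownames(frag_counts)[is.na(idx)]
    stop("unmapped fragment(s): ", paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ...")
  }
  out <- rowsum(frag_counts, group = map$protein_id[idx])
  storage.mode(out) <- "integer"
  out
}

#' Counts per million
#'
#' @param counts non-negative count matrix (features x samples).
#' @return matrix whose columns sum to 1e6.
#' @export
cpm <- function(counts) {
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop("all-zero column(s): ",
         paste(colnames(counts)[zero] %||% which(zero), collapse = ", "))
  }
  sweep(counts, 2L, cs, "/") * 1e6
}

#' Log2 counts-per-million with pseudocount
#'
#' @param counts count matrix.
#' @param pseudocount added before the log (default 1).
#' @return `log2(CPM + pseudocount)` matrix.
#' @export
log_cpm <- function(counts, pseudocount = 1) {
  log2(cpm(counts) + pseudocount)
}

#' Estimate per-batch correction factors from input-library controls
#'
#' Every sequencing batch carries an unselected input-library control.
#' The per-batch, per-antigen factor is the ratio of that batch's control
#' CPM (median across controls when a batch has several) to the
#' across-batch reference (mean of control CPM), with a pseudocount.
#' Dividing a batch's columns by its factors removes multiplicative
#' batch effects.
#'
#' @param counts antigen x sample count matrix (controls included).
#' @param meta sample metadata with `sample_id`, `batch`, `is_control`.
#' @param eps CPM pseudocount inside the ratio.
#' @param r2_threshold flag batches whose control-vs-reference log-CPM
#'   R-squared falls below this.
#' @return list with `factors` (antigen x batch matrix), `report`
#'   (per-batch control R-squared and flag), `reference` (CPM vector).
#' @export
estimate_batch_factors <- function(counts, meta, eps = 0.5,
                                   r2_threshold = 0.9) {
  ctrl <- meta$sample_id[meta$is_control]
  if (length(ctrl) == 0L) stop("no input-library control samples")
  batches <- sort(unique(meta$batch))
  no_ctrl <- setdiff(batches, meta$batch[meta$is_control])
  if (length(no_ctrl)) {
    stop("batch(es) without a control: ", paste(no_ctrl, collapse = ", "))
  }
  ctrl_cpm <- cpm(counts[, ctrl, drop = FALSE])
  ref <- rowMeans(ctrl_cpm)
  factors <- vapply(batches, function(b) {
    cols <- meta$sample_id[meta$is_control & meta$batch == b]
    bc <- ctrl_cpm[, cols, drop = FALSE]
    med <- apply(bc, 1L, median)
    (med + eps) / (ref + eps)
  }, numeric(nrow(counts)))
  colnames(factors) <- batches
  r2 <- vapply(batches, function(b) {
    cols <- meta$sample_id[meta$is_control & meta$batch == b]
    med <- apply(ctrl_cpm[, cols, drop = FALSE], 1L, median)
    # degenerate (constant) controls have no defined R-squared
    tryCatch(replicate_r2(log10(med + 1), log10(ref + 1)),
             error = function(e) NA_real_)
  }, numeric(1))
  list(factors = factors,
       report = data.frame(batch = batches, control_r2 = r2,
                           flagged = !is.na(r2) & r2 < r2_threshold),
       reference = ref)
}

#' Apply batch factors to a count matrix
#'
#' @param counts antigen x sample matrix.
#' @param meta metadata with `sample_id` and `batch`.
#' @param factors antigen x batch factor matrix from
#'   [estimate_batch_factors()].
#' @return corrected (numeric) matrix.
#' @export
apply_batch_factors <- function(counts, meta, factors) {
  b <- meta$batch[match(colnames(counts), meta$sample_id)]
  counts / factors[, as.character(b), drop = FALSE]
}

#' Binary selection call against the input library
#'
#' An antigen is called selected in a sample iff its raw count is at
#' least `min_count` and its CPM is at least `fold_threshold` times the
#' input-library CPM (pseudocount `eps` on both sides of the ratio).
#'
#' @param sample_cpm,input_cpm aligned CPM vectors (same antigen order;
#'   names checked when present).
#' @param raw_counts raw counts for the sample.
#' @param fold_threshold enrichment threshold F (default 5).
#' @param min_count minimum raw count c (default 10).
#' @param eps CPM pseudocount (default 0.5).
#' @return integer 0/1 vector.
#' @export
call_selected <- function(sample_cpm, input_cpm, raw_counts,
                          fold_threshold = 5, min_count = 10, eps = 0.5) {
  if (length(sample_cpm) != length(input_cpm)) {
    stop("sample and input vectors differ in length")
  }
  if (!is.null(names(sample_cpm)) && !is.null(names(input_cpm)) &&
      !identical(names(sample_cpm), names(input_cpm))) {
    stop("mismatched antigen IDs between sample and input")
  }
  as.integer(raw_counts >= min_count &
               (sample_cpm + eps) / (input_cpm + eps) >= fold_threshold)
}

#' Selection calls for a whole matrix
#'
#' @param counts antigen x sample count matrix.
#' @param input_cpm reference input-library CPM vector (e.g. the
#'   `reference` from [estimate_batch_factors()]).
#' @param ... thresholds passed to [call_selected()].
#' @return binary antigen x sample matrix with the thresholds recorded in
#'   attribute `thresholds`.
#' @export
call_selected_matrix <- function(counts, input_cpm, ...) {
  x <- cpm(counts)
  calls <- vapply(seq_len(ncol(x)), function(j) {
    call_selected(x[, j], input_cpm, counts[, j], ...)
  }, integer(nrow(x)))
  dimnames(calls) <- dimnames(counts)
  structure(calls, thresholds = list(...))
}

#' Per-group antigen prevalence from binary calls
#'
#' Prevalence = fraction of a group's donors whose sample selects the
#' antigen (one sample per donor: filter `meta` to one time point first).
#'
#' @param calls binary antigen x sample matrix.
#' @param meta metadata for the call columns (`sample_id`, `group`).
#' @return antigen x group prevalence matrix.
#' @export
prevalence_table <- function(calls, meta) {
  meta <- meta[match(colnames(calls), meta$sample_id), ]
  groups <- unique(meta$group)
  out <- vapply(groups, function(g) {
    rowMeans(calls[, meta$group == g, drop = FALSE])
  }, numeric(nrow(calls)))
  colnames(out) <- groups
  out
}

#' Replicate agreement as squared correlation
#'
#' The coefficient of determination of the least-squares line between two
#' replicate profiles (squared Pearson correlation; symmetric).  Pass
#' log-scale values for the conventional scatter-plot readout.
#'
#' @param a,b numeric vectors, equal length >= 3.
#' @return R-squared in `[0, 1]`.
#' @export
#' @examples
#' replicate_r2(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.64
replicate_r2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("vectors must have equal length >= 3")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("R-squared undefined: zero variance in one of the vectors")
  }
  cor(a, b)^2
}

#' Percent agreement between two binary call vectors
#'
#' @param calls_a,calls_b binary vectors of equal length.
#' @return percent of positions with identical calls, in `[0, 100]`.
#' @export
binary_agreement <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) stop("length mismatch")
  100 * mean(calls_a == calls_b)
}
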