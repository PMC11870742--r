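# Small fixtures built in code.

# hand-built fragment pool: explicit coordinates, no randomness
toy_pool <- function() {
  df <- data.frame(
    fragment_id = c("F1", "F2", "F3", "F4"),
    protein_id = c("P1", "P1", "P2", "P2"),
    source = c("A", "A", "B", "B"),
    seq = c(strrep("ATG", 10), strrep("AAA", 8),
            strrep("GGC", 12), strrep("TTC", 6)),
    orientation = "+",
    frame = 0L,
    start = c(0L, 30L, 0L, 36L),
    end = c(30L, 54L, 36L, 54L),
    stringsAsFactors = FALSE)
  df$aa_start <- df$start %/% 3L
  df$aa_end <- (df$end + 2L) %/% 3L
  df$input_abundance <- rep(0.25, 4)
  structure(df, class = c("FragmentPool", "data.frame"),
            protein_lengths = c(P1 = 18L, P2 = 18L))
}

random_aa <- function(n, len) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aas, len, replace = TRUE), collapse = "")
  }, character(1))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# brute-force stop-codon scan, independent of screen_orf()
oracle_orf <- function(seq, orientation, frame) {
  if (orientation == "-") return("wrong_orientation")
  stops <- c("TAA", "TAG", "TGA")
  i <- frame + 1L
  while (i + 2L <= nchar(seq)) {
    if (substr(seq, i, i + 2L) %in% stops) return("stop_in_frame")
    i <- i + 3L
  }
  "pass"
}

# brute-force BH step-up: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    qs[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- qs
  q
}

# small end-to-end simulated dataset shared by profile/differential tests
small_screen <- function(seed = 42, n_proteins = 150, groups = NULL,
                         pool_size = 8, prevalence = 0.6, fold = 10,
                         timepoints = 0, depth = 5e4) {
  groups <- groups %||% c(HC = 12, "PBO-A" = 6, "PBO-NA" = 6)
  pr <- generate_proteome(n_proteins, seed = seed)
  pool <- build_fragment_library(pr, candidates_per_source = 5 * n_proteins,
                                 seed = seed + 1)
  co <- generate_serum_cohort(
    pr, design = list(groups = groups, timepoints = timepoints),
    disease_pool = if (pool_size > 0)
      list(n_antigens = pool_size, prevalence = prevalence,
           hc_prevalence = 0.02, fold = fold) else NULL,
    seed = seed + 2)
  cnt <- simulate_cohort_screens(pool, co, depth = depth, seed = seed + 3)
  ag <- aggregate_fragments_to_antigens(cnt, pool)
  list(proteome = pr, pool = pool, cohort = co, frag_counts = cnt,
       antigen_counts = ag, meta = co$manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
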