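# Synthetic serological screens with known ground truth.
#
# The generator emulates the statistical structure of a pooled
# phage-display screen: four cell sources contribute proteins with
# heavy-tailed expression; candidate cDNA fragments are drawn with
# per-source insert-size distributions and funnelled through the
# two-plasmid ORF screen; donors carry idiosyncratic antibody targets plus
# (for cases) group-shared planted disease antigens; immunoselection is
# multiplicative enrichment over input abundance; sequencing is
# multinomial (Dirichlet-multinomial when overdispersed) at fixed depth.

default_sources <- c("HEp2", "astrocyte", "WBM", "PBMC")

#' Generate a simulated proteome
#'
#' Proteins are stop-free codon strings (first codon ATG) whose amino-acid
#' lengths are log-normal.  Each of four cell sources expresses a shared
#' common core of proteins plus additional proteins drawn independently;
#' expressed proteins get heavy-tailed (log-normal) relative abundances.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_dist list with `meanlog`, `sdlog` (log amino-acid length)
#'   and `min` (minimum residues).
#' @param overlap_config list with `p_core` (fraction of proteins shared
#'   by all sources), `p_extra` (probability each remaining protein is
#'   expressed in a given source), or an explicit logical `membership`
#'   matrix (proteins x sources).
#' @param expr_sdlog log-sd of per-source protein abundance (heavy tail).
#' @param sources source names (default 4 cell sources).
#' @param seed integer seed.
#' @return a `SimulatedProteome`: list with `proteins` (data frame
#'   `protein_id`, `aa`, `nt`, `length_aa`) and `expression`
#'   (proteins x sources matrix, 0 where unexpressed).
#' @export
generate_proteome <- function(n_proteins,
                              length_dist = list(meanlog = log(350),
                                                 sdlog = 0.45, min = 60),
                              overlap_config = list(p_core = 0.45,
                                                    p_extra = 0.35),
                              expr_sdlog = 1.6,
                              sources = default_sources,
                              seed = 1L) {
  if (n_proteins < 1) stop("configuration error: n_proteins must be >= 1")
  for (f in c("meanlog", "sdlog", "min")) {
    if (is.null(length_dist[[f]]) || !is.finite(length_dist[[f]])) {
      stop("configuration error: length_dist$", f, " invalid")
    }
  }
  if (length_dist$sdlog < 0 || length_dist$min < 1) {
    stop("configuration error: length_dist must be strictly positive")
  }
  with_seed(seed, {
    lens <- pmax(round(rlnorm(n_proteins, length_dist$meanlog,
                              length_dist$sdlog)), length_dist$min)
    ct <- codon_table()
    # residues uniform over the 20 standard amino acids, then a random
    # synonymous codon per residue (uniform codon sampling would skew the
    # composition toward residues with large codon families, e.g. Arg)
    codons_of <- split(names(ct), ct)
    codons_of <- codons_of[setdiff(names(codons_of), "*")]
    residues <- names(codons_of)
    nt <- vapply(lens, function(L) {
      aa_chain <- c("M", sample(residues, L - 1L, replace = TRUE))
      paste(vapply(codons_of[aa_chain], function(cs) {
        if (length(cs) == 1L) cs else sample(cs, 1L)
      }, character(1)), collapse = "")
    }, character(1))
    aa <- vapply(nt, function(s) {
      paste(ct[split_codons(s)], collapse = "")
    }, character(1), USE.NAMES = FALSE)
    ids <- sprintf("PROT%05d", seq_len(n_proteins))

    if (!is.null(overlap_config$membership)) {
      member <- overlap_config$membership
      stopifnot(nrow(member) == n_proteins, ncol(member) == length(sources))
    } else {
      p_core <- overlap_config$p_core %||% 0.45
      p_extra <- overlap_config$p_extra %||% 0.35
      if (p_core < 0 || p_core > 1) {
        stop("configuration error: overlap_config$p_core not in [0,1]")
      }
      if (p_extra < 0 || p_extra > 1) {
        stop("configuration error: overlap_config$p_extra not in [0,1]")
      }
      member <- matrix(FALSE, n_proteins, length(sources))
      n_core <- round(p_core * n_proteins)
      if (n_core > 0) member[seq_len(n_core), ] <- TRUE
      if (n_core < n_proteins) {
        rest <- (n_core + 1L):n_proteins
        member[rest, ] <- matrix(runif(length(rest) * length(sources)) <
                                   p_extra,
                                 length(rest), length(sources))
        none <- rest[rowSums(member[rest, , drop = FALSE]) == 0L]
        if (length(none)) {
          member[cbind(none, sample.int(length(sources), length(none),
                                        replace = TRUE))] <- TRUE
        }
      }
    }
    dimnames(member) <- list(ids, sources)
    expr <- matrix(0, n_proteins, length(sources),
                   dimnames = list(ids, sources))
    expr[member] <- rlnorm(sum(member), meanlog = 0, sdlog = expr_sdlog)

    structure(list(
      proteins = data.frame(protein_id = ids, aa = aa, nt = nt,
                            length_aa = lens, stringsAsFactors = FALSE),
      expression = expr,
      sources = sources
    ), class = "SimulatedProteome")
  })
}

#' @export
print.SimulatedProteome <- function(x, ...) {
  cat("SimulatedProteome:", nrow(x$proteins), "proteins,",
      length(x$sources), "sources\n")
  cat("  mean length:", round(mean(x$proteins$length_aa)), "aa\n")
  invisible(x)
}

#' Build a phage fragment library through the ORF-screen funnel
#'
#' Candidate fragments are drawn per source (protein chosen with
#' probability proportional to its source expression; start position
#' uniform on the coding sequence; insert length normal with per-source
#' mean/sd in bp; cloning frame uniform in `{0,1,2}`; orientation flipped
#' with probability `orientation_flip_p`).  A candidate enters the pool
#' iff [screen_orf()] accepts it.  Sources are pooled equally by phage
#' number: per-source input abundance is normalised before pooling.
#'
#' @param proteome a `SimulatedProteome`.
#' @param candidates_per_source number of candidate inserts per source.
#' @param insert_size_spec named list (per source) with `mean`, `sd` in
#'   bp.  Defaults span the observed per-library range of mean cDNA sizes
#'   (306 bp brain library to 482 bp HEp-2 library).
#' @param orientation_flip_p probability a candidate is cloned reversed.
#' @param min_insert minimum insert size in bp (>= 30).
#' @param abundance_sdlog log-sd of per-fragment abundance jitter.
#' @param seed integer seed.
#' @return a `FragmentPool`: data frame with columns `fragment_id`,
#'   `protein_id`, `source`, `seq`, `orientation`, `frame`, `start`,
#'   `end` (0-based half-open on the coding sequence), `aa_start`,
#'   `aa_end`, `input_abundance` (sums to 1).  Attributes: `funnel`
#'   (candidate/pass statistics) and `protein_lengths`.
#' @export
build_fragment_library <- function(proteome,
                                   candidates_per_source = 5L * nrow(proteome$proteins),
                                   insert_size_spec = list(
                                     HEp2 = list(mean = 482, sd = 160),
                                     astrocyte = list(mean = 400, sd = 140),
                                     WBM = list(mean = 306, sd = 100),
                                     PBMC = list(mean = 380, sd = 130)),
                                   orientation_flip_p = 0.05,
                                   min_insert = 30L,
                                   abundance_sdlog = 0.5,
                                   seed = 1L) {
  stopifnot(inherits(proteome, "SimulatedProteome"))
  if (min_insert < 30L) stop("configuration error: min_insert must be >= 30")
  if (nrow(proteome$proteins) == 0L) stop("proteome is empty")
  sources <- proteome$sources
  missing_spec <- setdiff(sources, names(insert_size_spec))
  if (length(missing_spec)) {
    stop("configuration error: insert_size_spec missing source(s) ",
         paste(missing_spec, collapse = ", "))
  }
  with_seed(seed, {
    nt <- proteome$proteins$nt
    nt_len <- nchar(nt)
    names(nt_len) <- proteome$proteins$protein_id
    out <- list()
    funnel <- list()
    n_skipped <- 0L
    for (src in sources) {
      expr <- proteome$expression[, src]
      ok <- expr > 0 & nt_len >= min_insert
      if (sum(expr > 0 & nt_len < min_insert) > 0) {
        n_skipped <- n_skipped + sum(expr > 0 & nt_len < min_insert)
      }
      if (!any(ok)) next
      pidx <- sample.int(length(expr), candidates_per_source,
                         replace = TRUE, prob = expr * ok)
      spec <- insert_size_spec[[src]]
      len <- pmax(round(rnorm(candidates_per_source, spec$mean, spec$sd)),
                  min_insert)
      len <- pmin(len, nt_len[pidx])
      start <- floor(runif(candidates_per_source) * (nt_len[pidx] - len + 1))
      frame <- sample(0:2, candidates_per_source, replace = TRUE)
      orient <- ifelse(runif(candidates_per_source) < orientation_flip_p,
                       "-", "+")
      seqs <- substring(nt[pidx], start + 1L, start + len)
      cls <- screen_orf_many(seqs, orient, frame)
      keep <- cls == "pass"
      funnel[[src]] <- list(candidates = candidates_per_source,
                            passed = sum(keep),
                            classes = table(cls),
                            candidate_codons = len %/% 3L)
      if (!any(keep)) next
      out[[src]] <- data.frame(
        protein_id = proteome$proteins$protein_id[pidx][keep],
        source = src,
        seq = seqs[keep],
        orientation = orient[keep],
        frame = frame[keep],
        start = as.integer(start[keep]),
        end = as.integer(start[keep] + len[keep]),
        stringsAsFactors = FALSE)
    }
    if (n_skipped > 0) {
      warning(n_skipped, " protein-source pairs shorter than the minimum ",
              "insert were skipped")
    }
    pool <- do.call(rbind, out)
    if (is.null(pool) || nrow(pool) == 0L) {
      stop("no candidate fragment passed the ORF screen")
    }
    rownames(pool) <- NULL
    pool$fragment_id <- sprintf("FRAG%06d", seq_len(nrow(pool)))
    pool$aa_start <- pool$start %/% 3L
    prot_len_aa <- setNames(proteome$proteins$length_aa,
                            proteome$proteins$protein_id)
    pool$aa_end <- pmin((pool$end + 2L) %/% 3L, prot_len_aa[pool$protein_id])
    # per-fragment input abundance: source expression x log-normal jitter,
    # normalised within source, sources pooled equally by phage number
    w <- proteome$expression[cbind(match(pool$protein_id,
                                         proteome$proteins$protein_id),
                                   match(pool$source, sources))]
    w <- w * rlnorm(nrow(pool), 0, abundance_sdlog)
    for (src in unique(pool$source)) {
      i <- pool$source == src
      w[i] <- w[i] / sum(w[i])
    }
    pool$input_abundance <- w / sum(w)
    pool <- pool[, c("fragment_id", "protein_id", "source", "seq",
                     "orientation", "frame", "start", "end",
                     "aa_start", "aa_end", "input_abundance")]
    structure(pool, class = c("FragmentPool", "data.frame"),
              funnel = funnel, protein_lengths = prot_len_aa)
  })
}

#' Generate a serum cohort with planted ground truth
#'
#' Every donor carries Poisson-many idiosyncratic antibody targets
#' (protein subregions with log-normal reactivity folds).  Donors in case
#' groups additionally draw each planted disease-pool antigen with the
#' configured per-group prevalence; healthy controls draw with
#' `hc_prevalence`.  Targets persist across time points; idiosyncratic
#' targets are dropped with probability `drift` per later visit and
#' replaced.  Samples (donor x time point) are assigned to sequencing
#' batches; each batch receives one unselected input-library control and
#' per-batch per-protein log-normal multiplicative factors.
#'
#' @param proteome a `SimulatedProteome`.
#' @param design list: `groups` (named sizes; default the five-arm design
#'   43 HC / 27+21+27+27 cases), `timepoints` (months, default
#'   `c(0, 6, 24)`), `batch_size` (samples per batch, default 24).
#' @param disease_pool `NULL` for a null cohort, or list with
#'   `n_antigens` (or explicit `antigens`), `prevalence` (scalar or named
#'   per case group), `hc_prevalence`, `fold` (enrichment of a planted
#'   target over background).
#' @param background list: `targets_per_donor` (Poisson mean),
#'   `fold_meanlog`, `fold_sdlog` (idiosyncratic reactivity folds),
#'   `epitope_len` (min/max residues), `rate` (background polyreactivity
#'   in `[0,1]`).
#' @param drift per-visit idiosyncratic target turnover probability.
#' @param batch_sdlog log-sd of per-batch per-protein factors.
#' @param seed integer seed.
#' @return list with `profiles` (list of `SerumProfile`), `manifest`
#'   (sample metadata incl. input-library controls) and `truth`
#'   (a `TruthTable`).
#' @export
generate_serum_cohort <- function(proteome,
                                  design = list(),
                                  disease_pool = NULL,
                                  background = list(),
                                  drift = 0.03,
                                  batch_sdlog = 0.2,
                                  seed = 1L) {
  stopifnot(inherits(proteome, "SimulatedProteome"))
  groups <- design$groups %||% c("HC" = 43, "PBO-A" = 27, "PBO-NA" = 21,
                                 "RNF-A" = 27, "RNF-NA" = 27)
  timepoints <- design$timepoints %||% c(0, 6, 24)
  batch_size <- design$batch_size %||% 24L
  if (any(groups < 0)) stop("configuration error: design$groups negative")
  bg <- list(targets_per_donor = 20, fold_meanlog = log(20),
             fold_sdlog = 1, epitope_len = c(30L, 120L), rate = 1)
  bg[names(background)] <- background
  if (bg$rate < 0 || bg$rate > 1) {
    stop("configuration error: background$rate not in [0,1]")
  }
  ids <- proteome$proteins$protein_id
  lens <- setNames(proteome$proteins$length_aa, ids)

  pool_antigens <- character(0)
  prev_of <- function(group) 0
  fold <- 1
  if (!is.null(disease_pool)) {
    prevs <- disease_pool$prevalence %||% 0.3
    if (any(prevs > 0)) {
      pool_antigens <- disease_pool$antigens %||% character(0)
      n_pool <- disease_pool$n_antigens %||% length(pool_antigens)
      if (length(pool_antigens) == 0L && (is.null(n_pool) || n_pool == 0L)) {
        stop("configuration error: disease_pool empty with prevalence > 0")
      }
      fold <- disease_pool$fold %||% 10
      hc_prev <- disease_pool$hc_prevalence %||% 0
      prev_of <- function(group) {
        if (group == "HC") return(hc_prev)
        if (is.null(names(prevs))) return(prevs[[1]])
        v <- prevs[group]
        if (is.na(v)) 0 else unname(v)
      }
    }
  }

  with_seed(seed, {
    if (!is.null(disease_pool) && length(pool_antigens) == 0L &&
        (disease_pool$n_antigens %||% 0) > 0) {
      pool_antigens <- sample(ids, disease_pool$n_antigens)
    }
    profiles <- list()
    donor_rows <- list()
    k <- 0L
    for (g in names(groups)) {
      ng <- groups[[g]]
      if (ng == 0) next
      for (d in seq_len(ng)) {
        k <- k + 1L
        donor_id <- sprintf("%s_%02d", gsub("-", "", g), d)
        n_t <- rpois(1L, bg$targets_per_donor)
        t_prot <- if (n_t > 0) sample(ids, min(n_t, length(ids))) else character(0)
        mk_targets <- function(prot) {
          if (length(prot) == 0L) {
            return(data.frame(protein_id = character(0), aa_start = integer(0),
                              aa_end = integer(0), reactivity = numeric(0),
                              stringsAsFactors = FALSE))
          }
          el <- pmin(round(runif(length(prot), bg$epitope_len[1],
                                 bg$epitope_len[2])), lens[prot])
          st <- floor(runif(length(prot)) * (lens[prot] - el + 1))
          data.frame(protein_id = prot,
                     aa_start = as.integer(st),
                     aa_end = as.integer(st + el),
                     reactivity = bg$rate *
                       (rlnorm(length(prot), bg$fold_meanlog, bg$fold_sdlog)),
                     stringsAsFactors = FALSE)
        }
        idio <- mk_targets(t_prot)
        planted <- character(0)
        pi_g <- prev_of(g)
        if (length(pool_antigens) && pi_g > 0) {
          planted <- pool_antigens[runif(length(pool_antigens)) < pi_g]
        }
        planted_targets <- if (length(planted)) {
          # disease antigens: whole-protein reactivity at the configured fold
          data.frame(protein_id = planted, aa_start = 0L,
                     aa_end = as.integer(lens[planted]),
                     reactivity = bg$rate * (fold - 1),
                     stringsAsFactors = FALSE)
        } else {
          idio[0, ]
        }
        # idiosyncratic target turnover across visits
        targets_by_time <- list()
        cur <- idio
        for (tp in timepoints) {
          if (length(targets_by_time)) {
            keep <- runif(nrow(cur)) >= drift
            n_new <- rpois(1L, drift * max(nrow(idio), 1))
            cur <- rbind(cur[keep, , drop = FALSE],
                         mk_targets(if (n_new > 0) sample(ids, n_new)
                                    else character(0)))
          }
          targets_by_time[[as.character(tp)]] <-
            rbind(cur, planted_targets)
        }
        profiles[[donor_id]] <- structure(list(
          donor_id = donor_id, group = g,
          timepoints = timepoints,
          background = bg$rate,
          targets_by_time = targets_by_time,
          planted = planted
        ), class = "SerumProfile")
        donor_rows[[donor_id]] <- data.frame(
          donor_id = donor_id, group = g, stringsAsFactors = FALSE)
      }
    }
    donors <- do.call(rbind, donor_rows)
    manifest <- do.call(rbind, lapply(timepoints, function(tp) {
      data.frame(sample_id = sprintf("%s_T%g", donors$donor_id, tp),
                 donor_id = donors$donor_id, group = donors$group,
                 timepoint = tp, stringsAsFactors = FALSE)
    }))
    manifest <- manifest[order(manifest$donor_id, manifest$timepoint), ]
    rownames(manifest) <- NULL
    # batch plan: shuffle samples into chunks, one input control per batch
    ord <- sample.int(nrow(manifest))
    batch <- integer(nrow(manifest))
    batch[ord] <- ceiling(seq_along(ord) / batch_size)
    manifest$batch <- batch
    manifest$is_control <- FALSE
    n_batches <- max(batch)
    controls <- data.frame(
      sample_id = sprintf("INPUT_B%02d", seq_len(n_batches)),
      donor_id = "INPUT", group = "input", timepoint = NA_real_,
      batch = seq_len(n_batches), is_control = TRUE,
      stringsAsFactors = FALSE)
    manifest <- rbind(manifest, controls)
    batch_factors <- matrix(
      rlnorm(length(ids) * n_batches, 0, batch_sdlog),
      nrow = length(ids), dimnames = list(ids, seq_len(n_batches)))

    truth <- structure(list(
      planted_antigens = pool_antigens,
      fold = fold,
      prevalence = if (length(pool_antigens))
        vapply(names(groups), prev_of, numeric(1)) else NULL,
      donor_planted = lapply(profiles, function(p) p$planted),
      batch_sdlog = batch_sdlog,
      batch_factors = batch_factors
    ), class = "TruthTable")
    list(profiles = profiles, manifest = manifest, truth = truth)
  })
}

#' Simulate one immunoselection screen
#'
#' Expected post-selection weight of a fragment is
#' `input_abundance * (background + sum of reactivities of overlapping
#' epitopes) * batch_factor`.  Counts are multinomial at the stated depth;
#' with finite `concentration` a Dirichlet-multinomial is used
#' (fragment probabilities jittered as normalised Gamma(p*concentration)).
#'
#' @param pool a `FragmentPool`.
#' @param profile a `SerumProfile` (or `NULL` for an input-library
#'   control).
#' @param timepoint which visit's targets to use (default first).
#' @param depth total read count (>= 0; 0 yields an all-zero vector).
#' @param concentration Dirichlet concentration; `Inf` = pure multinomial.
#' @param batch_factors optional per-protein multiplicative factors.
#' @param seed optional seed.
#' @return integer count vector named by fragment id, summing to `depth`.
#' @export
simulate_screen <- function(pool, profile, timepoint = NULL, depth = 1e5,
                            concentration = 1e4, batch_factors = NULL,
                            seed = NULL) {
  stopifnot(inherits(pool, "FragmentPool"))
  with_seed(seed, {
    w <- screen_weights(pool, profile, timepoint, batch_factors)
    counts <- integer(nrow(pool))
    if (depth >= 1) {
      p <- w / sum(w)
      if (is.finite(concentration)) {
        a <- rgamma(length(p), shape = p * concentration)
        if (sum(a) == 0) a <- p
        p <- a / sum(a)
      }
      counts <- as.integer(rmultinom(1L, size = depth, prob = p))
    }
    names(counts) <- pool$fragment_id
    counts
  })
}

# expected (unnormalised) selection weights for one sample
screen_weights <- function(pool, profile, timepoint = NULL,
                           batch_factors = NULL) {
  bg <- if (is.null(profile)) 1 else profile$background
  w <- pool$input_abundance * bg
  if (!is.null(profile)) {
    tp <- as.character(timepoint %||% profile$timepoints[1])
    targets <- profile$targets_by_time[[tp]]
    if (is.null(targets)) stop("profile has no targets for timepoint ", tp)
    if (nrow(targets)) {
      unknown <- setdiff(targets$protein_id, pool$protein_id)
      unknown <- setdiff(unknown, names(attr(pool, "protein_lengths") %||%
                                          character()))
      if (length(unknown)) {
        stop("internal consistency error: target protein(s) absent from ",
             "pool: ", paste(head(unknown, 3), collapse = ", "))
      }
      for (i in seq_len(nrow(targets))) {
        hit <- pool$protein_id == targets$protein_id[i] &
          pool$aa_start < targets$aa_end[i] &
          pool$aa_end > targets$aa_start[i]
        if (any(hit)) {
          w[hit] <- w[hit] + pool$input_abundance[hit] * targets$reactivity[i]
        }
      }
    }
  }
  if (!is.null(batch_factors)) {
    w <- w * batch_factors[pool$protein_id]
  }
  w
}

#' Simulate sequencing counts for a whole cohort
#'
#' Runs [simulate_screen()] for every manifest row (donor samples use the
#' donor's serum profile at the sample's time point; input-library control
#' samples use background-only weights) with per-batch factors applied.
#'
#' @param pool a `FragmentPool`.
#' @param cohort output of [generate_serum_cohort()].
#' @param depth,concentration passed to [simulate_screen()].
#' @param seed integer seed.
#' @return fragment-level count matrix (fragments x samples).
#' @export
simulate_cohort_screens <- function(pool, cohort, depth = 1e5,
                                    concentration = 1e4, seed = 1L) {
  manifest <- cohort$manifest
  bf <- cohort$truth$batch_factors
  with_seed(seed, {
    counts <- matrix(0L, nrow = nrow(pool), ncol = nrow(manifest),
                     dimnames = list(pool$fragment_id, manifest$sample_id))
    for (j in seq_len(nrow(manifest))) {
      prof <- if (manifest$is_control[j]) NULL else
        cohort$profiles[[manifest$donor_id[j]]]
      counts[, j] <- simulate_screen(
        pool, prof, timepoint = manifest$timepoint[j], depth = depth,
        concentration = concentration,
        batch_factors = bf[, manifest$batch[j]])
    }
    counts
  })
}

#' Write a simulated dataset to disk
#'
#' Emits fragment FASTA (and protein FASTA when a proteome is supplied),
#' a fragment-to-protein map TSV, fragment- and antigen-level count
#' tables, sample metadata TSV, and the truth table as JSON.  All files
#' round-trip through [read_dataset()].
#'
#' @param pool a `FragmentPool`.
#' @param cohort output of [generate_serum_cohort()].
#' @param frag_counts fragment-level count matrix.
#' @param out_dir output directory (created if missing).
#' @param proteome optional `SimulatedProteome`.
#' @return invisibly, the vector of files written.
#' @export
emit_dataset <- function(pool, cohort, frag_counts, out_dir,
                         proteome = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  p <- function(f) file.path(out_dir, f)
  frs <- Biostrings::DNAStringSet(setNames(pool$seq, pool$fragment_id))
  Biostrings::writeXStringSet(frs, p("fragments.fasta"))
  if (!is.null(proteome)) {
    prs <- Biostrings::AAStringSet(setNames(proteome$proteins$aa,
                                            proteome$proteins$protein_id))
    Biostrings::writeXStringSet(prs, p("proteins.fasta"))
  }
  map <- as.data.frame(pool)[, c("fragment_id", "protein_id", "source",
                                 "orientation", "frame", "start", "end",
                                 "aa_start", "aa_end", "input_abundance")]
  write.table(map, p("fragment_map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_tsv(frag_counts, p("fragment_counts.tsv"))
  ag <- aggregate_fragments_to_antigens(frag_counts, pool)
  write_count_tsv(ag, p("antigen_counts.tsv"))
  write.table(cohort$manifest, p("sample_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth_json <- list(
    planted_antigens = truth$planted_antigens,
    fold = truth$fold,
    prevalence = as.list(truth$prevalence),
    donor_planted = truth$donor_planted,
    batch_sdlog = truth$batch_sdlog,
    batch_factors = truth$batch_factors
  )
  jsonlite::write_json(truth_json, p("truth.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "columnmajor")
  invisible(c("fragments.fasta", "fragment_map.tsv", "fragment_counts.tsv",
              "antigen_counts.tsv", "sample_meta.tsv", "truth.json"))
}

write_count_tsv <- function(mat, path) {
  df <- data.frame(id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_count_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read back a dataset written by [emit_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `pool` (a `FragmentPool`, sequence column restored
#'   from the FASTA), `manifest`, `fragment_counts`, `antigen_counts`,
#'   `truth`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("fragments.fasta", "fragment_map.tsv", "fragment_counts.tsv",
              "antigen_counts.tsv", "sample_meta.tsv", "truth.json")) {
    if (!file.exists(p(f))) stop("missing dataset file: ", p(f))
  }
  frs <- Biostrings::readDNAStringSet(p("fragments.fasta"))
  map <- read.delim(p("fragment_map.tsv"), stringsAsFactors = FALSE)
  map$seq <- as.character(frs)[map$fragment_id]
  pool <- structure(map, class = c("FragmentPool", "data.frame"))
  truth <- jsonlite::read_json(p("truth.json"), simplifyVector = TRUE)
  list(pool = pool,
       manifest = read.delim(p("sample_meta.tsv"), stringsAsFactors = FALSE),
       fragment_counts = read_count_tsv(p("fragment_counts.tsv")),
       antigen_counts = read_count_tsv(p("antigen_counts.tsv")),
       truth = truth)
}
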