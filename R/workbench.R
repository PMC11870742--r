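# Orchestration: configuration handling and seeded end-to-end pipeline
# runs.  Configs are JSON; every run directory receives a normalised
# config copy and its hash so results are attributable and reproducible.

#' Default pipeline configuration
#'
#' The demo world: 2,000 proteins over four sources, 102 case donors
#' (four subgroups) plus 43 healthy controls at month 0, a planted
#' disease pool of 40 antigens at 35% case / 2% control prevalence and
#' 10-fold enrichment, sequencing depth 1e5 with mild overdispersion.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_format = "tsv",
    stages = list(simulate = TRUE, qc = TRUE, normalize = TRUE,
                  call = TRUE, diff = TRUE, enrich = TRUE, model = TRUE),
    simulate = list(
      n_proteins = 2000L,
      candidates_per_protein = 5,
      orientation_flip_p = 0.05,
      depth = 1e5,
      concentration = 1e4,
      design = list(
        groups = list("HC" = 43L, "PBO-A" = 27L, "PBO-NA" = 21L,
                      "RNF-A" = 27L, "RNF-NA" = 27L),
        timepoints = 0,
        batch_size = 24L),
      disease_pool = list(n_antigens = 40L, prevalence = 0.35,
                          hc_prevalence = 0.02, fold = 10),
      background = list(targets_per_donor = 20),
      drift = 0.03,
      batch_sdlog = 0.2),
    calls = list(fold_threshold = 5, min_count = 10, eps = 0.5),
    differential = list(min_prevalence = 0.01, p_threshold = 0.05,
                        q_threshold = 0.2,
                        reproducible_min_prevalence = 0.10),
    enrich = list(n_perm = 300L,
                  scales = c("chou_fasman_turn", "emini_accessibility",
                             "parker_hydrophilicity",
                             "gravy_hydrophobicity", "isoelectric_point",
                             "fraction_beta_turn", "fraction_beta_sheet")),
    model = list(K = 4L, L = 5L, q_threshold = 0.05,
                 prevalence_threshold = 0.30, nlambda = 100L,
                 lambda_min_ratio = 1e-3,
                 case_group = "PBO-A", control_group = "PBO-NA")
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]],
                                    paste0(path, k, "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

check_bound <- function(value, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(value) || any(value < lo) || any(value > hi)) {
    stop("configuration error: ", field, " must lie in [", lo, ", ", hi, "]")
  }
  invisible(TRUE)
}

#' Validate and normalise a pipeline configuration
#'
#' Reads a JSON file (or accepts a list), fills every missing field with
#' its default, rejects unknown keys, and checks bounds.  The returned
#' config is a fixed point of the function.
#'
#' @param config path to a JSON config, a list, or `NULL` for defaults.
#' @return normalised configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    config <- if (nzchar(trimws(txt))) {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    } else list()
  }
  cfg <- merge_config(default_config(), config)
  check_bound(cfg$differential$q_threshold, "differential$q_threshold", 0, 1)
  check_bound(cfg$differential$p_threshold, "differential$p_threshold", 0, 1)
  check_bound(cfg$differential$min_prevalence,
              "differential$min_prevalence", 0, 1)
  check_bound(cfg$differential$reproducible_min_prevalence,
              "differential$reproducible_min_prevalence", 0, 1)
  check_bound(cfg$model$q_threshold, "model$q_threshold", 0, 1)
  check_bound(cfg$model$prevalence_threshold,
              "model$prevalence_threshold", 0, 1)
  check_bound(cfg$model$K, "model$K", 2)
  check_bound(cfg$model$L, "model$L", 2)
  check_bound(cfg$calls$fold_threshold, "calls$fold_threshold", 0)
  check_bound(cfg$simulate$depth, "simulate$depth", 0)
  check_bound(cfg$simulate$orientation_flip_p,
              "simulate$orientation_flip_p", 0, 1)
  if (!is.null(cfg$simulate$disease_pool$prevalence)) {
    check_bound(unlist(cfg$simulate$disease_pool$prevalence),
                "simulate$disease_pool$prevalence", 0, 1)
  }
  cfg
}

#' Hash of a normalised configuration
#'
#' @param config a (validated) configuration list.
#' @return md5 hex digest of the canonical JSON serialisation.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(con, stage, t0) {
  msg <- sprintf("%s\t%.2fs", stage,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeLines(msg, con)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline into a directory
#'
#' Stages run in order simulate, qc, normalize, call, diff, enrich,
#' model (each can be toggled off).  Every artifact directory receives
#' the normalised config, its hash, and a timing log.  A rerun with an
#' identical config reproduces identical outputs; a stage failure aborts
#' with the stage name while preserving the outputs already written.
#'
#' @param config config list/path for [validate_config()].
#' @param out_dir run directory (created).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = NULL, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(config_hash(cfg), file.path(out_dir, "config_hash.txt"))
  log_path <- file.path(out_dir, "run.log")
  logf <- file(log_path, open = "wt")
  on.exit(close(logf))
  res <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    pipeline_log(logf, name, t0)
    out
  }
  sim <- cfg$simulate
  data_dir <- file.path(out_dir, "dataset")

  if (isTRUE(cfg$stages$simulate)) {
    res$sim <- run_stage("simulate", {
      s <- child_seed(cfg$seed, "simulate")
      proteome <- generate_proteome(sim$n_proteins, seed = s)
      pool <- build_fragment_library(
        proteome,
        candidates_per_source = round(sim$candidates_per_protein *
                                        sim$n_proteins),
        orientation_flip_p = sim$orientation_flip_p, seed = s + 1L)
      groups <- unlist(sim$design$groups)
      cohort <- generate_serum_cohort(
        proteome,
        design = list(groups = groups, timepoints = sim$design$timepoints,
                      batch_size = sim$design$batch_size),
        disease_pool = sim$disease_pool,
        background = sim$background,
        drift = sim$drift, batch_sdlog = sim$batch_sdlog, seed = s + 2L)
      frag_counts <- simulate_cohort_screens(
        pool, cohort, depth = sim$depth,
        concentration = sim$concentration, seed = s + 3L)
      emit_dataset(pool, cohort, frag_counts, data_dir, proteome = proteome)
      list(proteome = proteome, pool = pool, cohort = cohort,
           frag_counts = frag_counts)
    })
    pool <- res$sim$pool
    meta <- res$sim$cohort$manifest
    antigen_counts <- aggregate_fragments_to_antigens(res$sim$frag_counts,
                                                      pool)
  } else {
    ds <- read_dataset(data_dir)
    pool <- ds$pool
    meta <- ds$manifest
    antigen_counts <- ds$antigen_counts
    res$sim <- ds
  }

  if (isTRUE(cfg$stages$qc)) {
    res$qc <- run_stage("qc", {
      qc <- library_qc_summary(pool)
      jsonlite::write_json(
        list(insert_size = qc$insert_size,
             fragments_per_protein = qc$fragments_per_protein,
             complexity = list(per_source = as.list(qc$complexity$per_source),
                               venn = as.list(qc$complexity$venn),
                               union_size = qc$complexity$union_size),
             funnel = lapply(qc$funnel, function(f) {
               list(candidates = f$candidates, passed = f$passed,
                    classes = as.list(f$classes))
             })),
        file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
      qc
    })
  }

  if (isTRUE(cfg$stages$normalize)) {
    res$norm <- run_stage("normalize", {
      bf <- estimate_batch_factors(antigen_counts, meta)
      corrected <- apply_batch_factors(antigen_counts, meta, bf$factors)
      norm <- log_cpm(corrected)
      write_tsv(data.frame(antigen = rownames(norm),
                           round(as.data.frame(norm), 4),
                           check.names = FALSE),
                file.path(out_dir, "log_cpm.tsv"))
      write_tsv(bf$report, file.path(out_dir, "batch_report.tsv"))
      list(batch = bf, corrected = corrected, norm = norm)
    })
  }

  if (isTRUE(cfg$stages$call)) {
    res$calls <- run_stage("call", {
      calls <- call_selected_matrix(
        res$norm$corrected, res$norm$batch$reference,
        fold_threshold = cfg$calls$fold_threshold,
        min_count = cfg$calls$min_count, eps = cfg$calls$eps)
      write_count_tsv(calls, file.path(out_dir, "calls.tsv"))
      calls
    })
  }

  if (isTRUE(cfg$stages$diff)) {
    res$diff <- run_stage("diff", {
      base <- meta[!meta$is_control &
                     meta$timepoint == min(meta$timepoint, na.rm = TRUE), ]
      case_meta <- base[base$group != "HC", ]
      hc <- base$sample_id[base$group == "HC"]
      split <- split_set_reproducibility(
        res$norm$norm, res$calls, case_meta$sample_id, case_meta$group,
        hc, seed = child_seed(cfg$seed, "diff"),
        min_prevalence = cfg$differential$min_prevalence,
        p_threshold = cfg$differential$p_threshold,
        q_threshold = cfg$differential$q_threshold)
      prev_all <- rowMeans(res$calls[, case_meta$sample_id, drop = FALSE])
      final_hits <- prevalence_filter(
        split$reproducible, prev_all,
        cfg$differential$reproducible_min_prevalence)
      representation <- tapply(pool$input_abundance, pool$protein_id, sum)
      representation <- setNames(as.numeric(representation),
                                 names(representation))
      bias <- if (length(split$reproducible)) {
        rank_bias_diagnostic(
          intersect(split$reproducible, names(representation)),
          representation)
      } else NULL
      write_tsv(split$res1, file.path(out_dir, "differential_set1.tsv"))
      write_tsv(split$res2, file.path(out_dir, "differential_set2.tsv"))
      jsonlite::write_json(
        list(partition = lapply(split$partition, length),
             reproducible = split$reproducible,
             final_hits = final_hits,
             rank_bias = if (!is.null(bias))
               list(median = bias$median, range = bias$range) else NULL),
        file.path(out_dir, "differential_partition.json"),
        auto_unbox = TRUE, digits = NA)
      list(split = split, final_hits = final_hits, bias = bias,
           prevalence = prev_all)
    })
  }

  if (isTRUE(cfg$stages$enrich)) {
    res$enrich <- run_stage("enrich", {
      seqs <- setNames(res$sim$proteome$proteins$aa,
                       res$sim$proteome$proteins$protein_id)
      props <- protein_property_table(seqs)
      write_tsv(props, file.path(out_dir, "property_table.tsv"))
      hits <- res$diff$final_hits
      enr <- NULL
      if (length(hits) >= 3L) {
        enr <- lapply(cfg$enrich$scales, function(sc) {
          sub <- props[props$scale == sc, ]
          scores <- setNames(sub$score, sub$protein_id)
          r <- gsea_enrichment(scores, intersect(hits, names(scores)),
                               n_perm = cfg$enrich$n_perm,
                               seed = child_seed(cfg$seed, "enrich"))
          list(scale = sc, es = r$es, nes = r$nes, p = r$p)
        })
      }
      jsonlite::write_json(enr, file.path(out_dir, "enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      list(properties = props, enrichment = enr)
    })
  }

  if (isTRUE(cfg$stages$model)) {
    res$model <- run_stage("model", {
      base <- meta[!meta$is_control &
                     meta$timepoint == min(meta$timepoint, na.rm = TRUE), ]
      mcase <- base$sample_id[base$group == cfg$model$case_group]
      mctrl <- base$sample_id[base$group == cfg$model$control_group]
      hc <- base$sample_id[base$group == "HC"]
      dres <- differential_selection(
        res$norm$norm, res$calls, c(mcase, mctrl), hc,
        min_prevalence = cfg$differential$min_prevalence,
        p_threshold = cfg$differential$p_threshold,
        q_threshold = cfg$differential$q_threshold)
      labels <- setNames(rep(0L, length(mcase) + length(mctrl)),
                         c(mcase, mctrl))
      labels[mcase] <- 1L
      dm <- build_design_matrix(res$norm$norm, dres, labels,
                                q_threshold = cfg$model$q_threshold,
                                prevalence_threshold =
                                  cfg$model$prevalence_threshold)
      report <- nested_cv(dm$X, dm$y, K = cfg$model$K, L = cfg$model$L,
                          nlambda = cfg$model$nlambda,
                          lambda_min_ratio = cfg$model$lambda_min_ratio,
                          seed = child_seed(cfg$seed, "model"))
      jsonlite::write_json(
        list(auc = as.list(report$auc),
             lambda = report$final$lambda,
             retained = report$final$retained,
             coefficients = as.list(report$final$coefficients),
             effects = report$effects,
             folds = report$folds),
        file.path(out_dir, "model_report.json"), auto_unbox = TRUE,
        digits = NA)
      write_tsv(data.frame(sample_id = rownames(report$shap),
                           round(as.data.frame(report$shap), 6),
                           check.names = FALSE),
                file.path(out_dir, "shap.tsv"))
      report
    })
  }
  invisible(res)
}
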