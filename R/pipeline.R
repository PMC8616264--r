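#' Pipeline run configuration
#'
#' Assembles stage parameters and optional input paths for [run_all()].
#' Defaults re-enact the full protocol on synthetic data: BH-FDR 0.1,
#' fold-change 2, delta-beta 0.2, 80/20 class-balanced splits, 10-fold
#' CV, and consensus selection over repeated LASSO fits.
#'
#' @param n_islands Number of islands in the synthetic annotation.
#' @param count_cfg A [count_sim_config()] (rebuilt with `seed` if NULL).
#' @param beta_cfg A [beta_sim_config()] (rebuilt with `seed` if NULL).
#' @param q_max,fc_min,delta_min Calling thresholds.
#' @param k_top Top fold-change-ranked islands fed to the classifier.
#' @param n_repeats LASSO protocol repeats.
#' @param folds CV folds.
#' @param counts_path,samples_path,beta_path,beta_samples_path Optional
#'   paths to pre-made inputs replacing the simulation stage.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(n_islands = 300, count_cfg = NULL, beta_cfg = NULL,
                       q_max = 0.1, fc_min = 2, delta_min = 0.2,
                       k_top = 30, n_repeats = 20, folds = 10,
                       counts_path = NULL, samples_path = NULL,
                       beta_path = NULL, beta_samples_path = NULL,
                       seed = 1L) {
  stopifnot(q_max > 0, fc_min > 0, delta_min > 0)
  if (is.null(count_cfg)) count_cfg <- count_sim_config(seed = seed)
  if (is.null(beta_cfg)) beta_cfg <- beta_sim_config(seed = seed)
  structure(list(n_islands = n_islands, count_cfg = count_cfg,
                 beta_cfg = beta_cfg, q_max = q_max, fc_min = fc_min,
                 delta_min = delta_min, k_top = k_top,
                 n_repeats = n_repeats, folds = folds,
                 counts_path = counts_path, samples_path = samples_path,
                 beta_path = beta_path,
                 beta_samples_path = beta_samples_path,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()] arguments; `count_cfg`
#' and `beta_cfg` sub-maps onto [count_sim_config()] /
#' [beta_sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$count_cfg)) {
    raw$count_cfg <- do.call(count_sim_config, raw$count_cfg)
  }
  if (!is.null(raw$beta_cfg)) {
    bc <- raw$beta_cfg
    if (!is.null(bc$groups)) bc$groups <- unlist(bc$groups)
    raw$beta_cfg <- do.call(beta_sim_config, bc)
  }
  do.call(run_config, raw)
}

#' Validate pipeline input files
#'
#' Schema checks on the TSV inputs referenced by a config: counts must
#' be non-negative integers with every sample in the sample sheet; beta
#' values must lie in `[0, 1]`. Unrecognized extra columns and sheet
#' samples absent from the matrices produce warnings only.
#'
#' @param cfg A `run_config` with input paths set.
#' @param stop_on_fatal Abort (default) or return the report with
#'   accumulated messages.
#' @return List with `fatal`, `warnings` (character vectors) and `ok`.
#' @export
validate_inputs <- function(cfg, stop_on_fatal = TRUE) {
  fatal <- character(0)
  warn <- character(0)
  if (!is.null(cfg$counts_path)) {
    if (!file.exists(cfg$counts_path)) {
      fatal <- c(fatal, paste("counts_path does not exist:",
                              cfg$counts_path))
    } else if (is.null(cfg$samples_path) ||
               !file.exists(cfg$samples_path)) {
      fatal <- c(fatal, "samples_path missing for counts input")
    } else {
      df <- utils::read.table(cfg$counts_path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE)
      sheet <- utils::read.table(cfg$samples_path, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
      need <- c("feature_id", "class")
      if (!all(need %in% colnames(df))) {
        fatal <- c(fatal, "counts TSV lacks feature_id/class columns")
      } else {
        samples <- setdiff(colnames(df), need)
        missing <- setdiff(samples, sheet$sample)
        if (length(missing)) {
          fatal <- c(fatal, paste("samples in counts but not sample",
                                  "sheet:", paste(missing, collapse = ", ")))
        }
        extra_sheet <- setdiff(sheet$sample, samples)
        if (length(extra_sheet)) {
          warn <- c(warn, paste("sample sheet entries without a counts",
                                "column:",
                                paste(extra_sheet, collapse = ", ")))
        }
        vals <- as.matrix(df[, intersect(samples, sheet$sample),
                             drop = FALSE])
        if (any(vals < 0) || any(vals != round(vals))) {
          fatal <- c(fatal, "counts must be non-negative integers")
        }
      }
      extra_cols <- setdiff(colnames(sheet), c("sample", "group"))
      if (length(extra_cols)) {
        warn <- c(warn, paste("extra sample-sheet columns ignored:",
                              paste(extra_cols, collapse = ", ")))
      }
    }
  }
  if (!is.null(cfg$beta_path)) {
    if (!file.exists(cfg$beta_path)) {
      fatal <- c(fatal, paste("beta_path does not exist:", cfg$beta_path))
    } else if (is.null(cfg$beta_samples_path) ||
               !file.exists(cfg$beta_samples_path)) {
      fatal <- c(fatal, "beta_samples_path missing for beta input")
    } else {
      df <- utils::read.table(cfg$beta_path, sep = "\t", header = TRUE,
                              check.names = FALSE,
                              stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
      sheet <- utils::read.table(cfg$beta_samples_path, sep = "\t",
                                 header = TRUE, stringsAsFactors = FALSE)
      need <- c("site_id", "island_id")
      if (!all(need %in% colnames(df))) {
        fatal <- c(fatal, "beta TSV lacks site_id/island_id columns")
      } else {
        samples <- setdiff(colnames(df), need)
        missing <- setdiff(samples, sheet$sample)
        if (length(missing)) {
          fatal <- c(fatal, paste("samples in betas but not sample",
                                  "sheet:", paste(missing, collapse = ", ")))
        }
        vals <- as.matrix(df[, intersect(samples, sheet$sample),
                             drop = FALSE])
        if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
          fatal <- c(fatal, "beta values outside [0, 1]")
        }
      }
    }
  }
  report <- list(fatal = fatal, warnings = warn, ok = !length(fatal))
  if (stop_on_fatal && length(fatal)) {
    stop("input validation failed:\n  ", paste(fatal, collapse = "\n  "))
  }
  report
}

#' Run the full pipeline end to end
#'
#' Wires all stages in order: synthetic-data generation (or loading of
#' supplied inputs), spike-in QC, TPM/class-coverage QC, row filtering,
#' island subsetting, NB Wald differential methylation, array-side DMC
#' calling against normal tissue and PBMCs, island-set intersection to
#' tumor-derived DMCGIs, and the consensus-LASSO classifier on
#' island-level beta values of the top fold-change-ranked tumor-derived
#' islands. Returns a manifest of per-stage counts, parameters and
#' seeds; fully reproducible from config + seed.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory for intermediate artifacts
#'   (counts/beta TSVs, island-set files, manifest JSON).
#' @return Manifest list with per-stage results and counts.
#' @export
run_all <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  validate_inputs(cfg)

  # --- inputs: simulate or load -------------------------------------
  if (is.null(cfg$counts_path)) {
    ann <- simulate_island_annotation(cfg$n_islands)
    sim <- simulate_counts(cfg$count_cfg, ann)
    fcm <- sim$matrix
    truth <- sim$truth
  } else {
    ann <- NULL
    fcm <- read_count_matrix(cfg$counts_path, cfg$samples_path)
    truth <- NULL
  }

  # --- capture QC ----------------------------------------------------
  spike <- simulate_spikein(capture_eff_meth = 0.2,
                            capture_eff_unmeth = 0.001,
                            seed = cfg$seed)
  qc <- spikein_qc(spike)
  tpm <- tpm_normalize(fcm, lengths = rep(1000, nrow(fcm$counts)))
  coverage <- class_coverage_fractions(tpm, fcm$feature_class)

  # --- counting filters ---------------------------------------------
  n_input <- nrow(fcm$counts)
  filtered <- filter_matrix(fcm)
  islands_m <- subset_islands(filtered)

  # --- plasma differential methylation ------------------------------
  dm <- nb_wald_test(islands_m, q_max = cfg$q_max, fc_min = cfg$fc_min)
  calls <- call_dmcgi(dm, cfg$q_max, cfg$fc_min)

  # --- array harmonization ------------------------------------------
  island_ids <- rownames(islands_m$counts)
  if (is.null(cfg$beta_path)) {
    bm <- simulate_betas(cfg$beta_cfg, island_ids,
                         truth %||% list(planted_hyper = character(0)))
  } else {
    bm <- read_beta_matrix(cfg$beta_path, cfg$beta_samples_path)
  }
  dmc_n <- dmc_test(bm, comparator = "normal")
  dmc_p <- dmc_test(bm, comparator = "pbmc")
  set_n <- sites_to_island_set(dmc_n[call_dmc(dmc_n, cfg$delta_min,
                                              cfg$q_max), , drop = FALSE])
  set_p <- sites_to_island_set(dmc_p[call_dmc(dmc_p, cfg$delta_min,
                                              cfg$q_max), , drop = FALSE])

  # --- intersection --------------------------------------------------
  derived <- tumor_derived(calls$hyper, set_n, set_p)
  recovery_pct <- if (!is.null(truth) && length(truth$planted_hyper)) {
    overlap_percent(length(intersect(derived, truth$planted_hyper)),
                    length(truth$planted_hyper))
  } else NA_real_

  # --- classifier on island betas -----------------------------------
  report <- NULL
  if (length(derived) >= 2) {
    k <- min(cfg$k_top, length(derived))
    ranked <- top_features(dm, k, candidates = derived)
    ib <- collapse_island_betas(bm)
    X <- t(ib$betas[intersect(ranked, rownames(ib$betas)), , drop = FALSE])
    y <- ifelse(ib$group[rownames(X)] == "tumor", "tumor", "rest")
    report <- run_protocol(X, y, n_repeats = cfg$n_repeats,
                           folds = cfg$folds, positive = "tumor",
                           seed = cfg$seed)
  }

  manifest <- list(
    seed = cfg$seed,
    thresholds = list(q_max = cfg$q_max, fc_min = cfg$fc_min,
                      delta_min = cfg$delta_min),
    qc = list(specificity = qc$specificity, pass = qc$pass),
    coverage_island_median = stats::median(coverage$island),
    rows = list(input = n_input, filtered = nrow(filtered$counts),
                dropped = n_input - nrow(filtered$counts),
                islands = nrow(islands_m$counts)),
    planted = if (!is.null(truth)) {
      list(hyper = length(truth$planted_hyper),
           hypo = length(truth$planted_hypo))
    },
    dm = list(n_dmr = sum(dm$results$is_dmr, na.rm = TRUE),
              n_hyper = length(calls$hyper),
              n_hypo = length(calls$hypo)),
    array = list(dmcgi_vs_normal = length(set_n),
                 dmcgi_vs_pbmc = length(set_p)),
    tumor_derived = list(n = length(derived),
                         recovery_pct = recovery_pct),
    classifier = if (!is.null(report)) {
      list(consensus = report$consensus_set,
           auc_median = report$auc_median)
    },
    results = list(diffmeth = dm, report = report,
                   derived = derived, truth = truth))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(dm$results, file.path(out_dir, "diffmeth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_island_set(calls$hyper, file.path(out_dir, "plasma_hyper.txt"))
    write_island_set(derived, file.path(out_dir, "tumor_derived.txt"))
    slim <- manifest[setdiff(names(manifest), "results")]
    jsonlite::write_json(slim, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}

`%||%` <- function(a, b) if (is.null(a)) b else a
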