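#' Configuration for the count simulator
#'
#' Describes a synthetic capture-sequencing experiment: negative-binomial
#' feature counts with library-size variation, capture bias toward
#' CpG-dense classes, and a planted set of case-hypermethylated islands at
#' a chosen fold change. Defaults mirror a single-cancer-type plasma
#' cohort (12 cases vs 16 controls) with ~10% of islands planted
#' hypermethylated at fold change 4 and a small hypomethylated minority
#' (~0.2% of planted features), reflecting the strong hyper/hypo asymmetry
#' of CpG-island methylation in carcinoma.
#'
#' @param n_features Number of features to simulate (taken from the head
#'   of the supplied annotation; NULL = all).
#' @param n_cases,n_controls Group sample sizes.
#' @param baseline_mean Expected control count for an inter-CpG feature at
#'   library-size factor 1. Island/shore/shelf means are this baseline
#'   multiplied by `class_bias`.
#' @param class_bias Named multipliers modelling MBD capture bias
#'   (default island 30, shore 8, shelf 3, inter 1).
#' @param dispersion NB dispersion alpha, variance = mu + alpha mu^2.
#' @param libsize_range Interval of per-sample multiplicative library-size
#'   factors, drawn log-uniformly.
#' @param planted_fraction Proportion of island features planted as
#'   differentially methylated in cases.
#' @param planted_fc Fold change (> 1) applied to case means of planted
#'   hypermethylated islands; hypomethylated plantings use `1/planted_fc`.
#' @param hypo_fraction Proportion of planted features that are
#'   hypomethylated rather than hypermethylated.
#' @param seed RNG seed; identical configs give identical data.
#' @return A list of class `count_sim_config`.
#' @export
count_sim_config <- function(n_features = NULL, n_cases = 12, n_controls = 16,
                             baseline_mean = 2,
                             class_bias = c(island = 30, shore = 8,
                                            shelf = 3, inter = 1),
                             dispersion = 0.05,
                             libsize_range = c(0.5, 2),
                             planted_fraction = 0.1, planted_fc = 4,
                             hypo_fraction = 0.002, seed = 1L) {
  stopifnot(planted_fc > 0, dispersion >= 0,
            planted_fraction >= 0, planted_fraction <= 1,
            hypo_fraction >= 0, hypo_fraction <= 1,
            length(libsize_range) == 2, all(libsize_range > 0))
  structure(list(n_features = n_features, n_cases = n_cases,
                 n_controls = n_controls, baseline_mean = baseline_mean,
                 class_bias = class_bias, dispersion = dispersion,
                 libsize_range = libsize_range,
                 planted_fraction = planted_fraction,
                 planted_fc = planted_fc, hypo_fraction = hypo_fraction,
                 seed = as.integer(seed)),
            class = "count_sim_config")
}

#' Simulate a toy CpG island annotation
#'
#' Lays out `n_islands` islands of width `island_bp`, regularly spaced
#' with `gap_bp` between them, on as many synthetic chromosomes as
#' needed, then derives the shore/shelf/inter partition. Convenience
#' generator for exercising the pipeline on data with known geometry.
#'
#' @param n_islands Number of islands.
#' @param island_bp Island width in bp.
#' @param gap_bp Distance between island ends and the next island start.
#' @param islands_per_chrom Islands laid on each synthetic chromosome.
#' @return A feature data frame as from [derive_feature_classes()].
#' @export
simulate_island_annotation <- function(n_islands, island_bp = 1000,
                                       gap_bp = 20000,
                                       islands_per_chrom = 500) {
  n_chrom <- ceiling(n_islands / islands_per_chrom)
  isl <- list()
  sizes <- numeric(0)
  k <- 0
  for (ch in seq_len(n_chrom)) {
    chr <- paste0("chr", ch)
    n_here <- min(islands_per_chrom, n_islands - k)
    starts <- gap_bp + (seq_len(n_here) - 1) * (island_bp + gap_bp) + 1
    isl[[chr]] <- data.frame(chrom = chr, start = starts,
                             end = starts + island_bp - 1,
                             stringsAsFactors = FALSE)
    sizes[chr] <- starts[n_here] + island_bp - 1 + gap_bp
    k <- k + n_here
  }
  derive_feature_classes(do.call(rbind, isl), sizes)
}

#' Simulate NB feature counts with planted differential methylation
#'
#' Draws a features-by-samples count matrix from a negative binomial
#' model: `count_ij ~ NB(mean = libsize_j * mu_i * fc_ij, dispersion)`,
#' where `mu_i` is the class-biased baseline, and `fc_ij` is
#' `planted_fc` for planted hypermethylated islands in case samples
#' (`1/planted_fc` for the hypomethylated minority) and 1 otherwise.
#' Only island-class features are eligible for planting.
#'
#' @param cfg A [count_sim_config()].
#' @param features Feature annotation data frame (`feature_id`, `class`).
#' @return A list with elements `matrix` (a [feature_count_matrix()])
#'   and `truth` (list with `planted_hyper`, `planted_hypo` feature-id
#'   sets and `libsize` factors).
#' @export
simulate_counts <- function(cfg, features) {
  stopifnot(inherits(cfg, "count_sim_config"))
  if (!is.null(cfg$n_features)) {
    if (cfg$n_features > nrow(features)) {
      stop("annotation provides ", nrow(features),
           " features, config asks for ", cfg$n_features)
    }
    features <- features[seq_len(cfg$n_features), , drop = FALSE]
  }
  set.seed(cfg$seed)
  nf <- nrow(features)
  ns <- cfg$n_cases + cfg$n_controls
  group <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  samples <- sprintf("%s_%02d", group, c(seq_len(cfg$n_cases),
                                         seq_len(cfg$n_controls)))
  libsize <- exp(stats::runif(ns, log(cfg$libsize_range[1]),
                              log(cfg$libsize_range[2])))
  names(libsize) <- samples
  mu <- cfg$baseline_mean * cfg$class_bias[features$class]

  is_island <- features$class == "island"
  n_plant <- round(cfg$planted_fraction * sum(is_island))
  planted <- if (n_plant > 0) {
    sample(features$feature_id[is_island], n_plant)
  } else character(0)
  n_hypo <- round(cfg$hypo_fraction * n_plant)
  hypo <- if (n_hypo > 0) sample(planted, n_hypo) else character(0)
  hyper <- setdiff(planted, hypo)

  fc <- rep(1, nf)
  fc[features$feature_id %in% hyper] <- cfg$planted_fc
  fc[features$feature_id %in% hypo] <- 1 / cfg$planted_fc

  counts <- matrix(0L, nf, ns, dimnames = list(features$feature_id, samples))
  for (j in seq_len(ns)) {
    m <- libsize[j] * mu * (if (group[j] == "case") fc else rep(1, nf))
    counts[, j] <- if (cfg$dispersion > 0) {
      stats::rnbinom(nf, mu = m, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(nf, m)
    }
  }
  fcm <- feature_count_matrix(counts, features$class, group)
  list(matrix = fcm,
       truth = list(planted_hyper = sort(hyper), planted_hypo = sort(hypo),
                    libsize = libsize))
}

#' Configuration for the array beta-value simulator
#'
#' Emulates 450K-style CpG-site methylation fractions for three groups
#' (tumor, adjacent normal, PBMC). Sites on planted islands have tumor
#' mean `base_beta + delta`; all other site/group combinations have mean
#' `base_beta`. Values are Beta-distributed with precision
#' `concentration`. Defaults mirror a lung-sized harmonization cohort
#' (21 tumor/normal pairs, 61 PBMCs) with a planted mean difference of
#' 0.35 — comfortably above the 0.2 delta-beta calling threshold.
#'
#' @param n_sites_per_island CpG sites measured per island.
#' @param groups Named sample counts for tumor, normal, pbmc.
#' @param base_beta Mean methylation outside planted effects.
#' @param delta Planted tumor-vs-rest mean difference (base_beta + delta
#'   must stay in `[0, 1]`).
#' @param concentration Beta-distribution precision (a + b).
#' @param overlap_with_counts Proportion of count-planted islands also
#'   planted on the array side.
#' @param seed RNG seed.
#' @return A list of class `beta_sim_config`.
#' @export
beta_sim_config <- function(n_sites_per_island = 5,
                            groups = c(tumor = 21, normal = 21, pbmc = 61),
                            base_beta = 0.2, delta = 0.35,
                            concentration = 50,
                            overlap_with_counts = 1, seed = 1L) {
  stopifnot(base_beta >= 0, base_beta <= 1, concentration > 0,
            overlap_with_counts >= 0, overlap_with_counts <= 1,
            all(c("tumor", "normal", "pbmc") %in% names(groups)))
  if (base_beta + delta < 0 || base_beta + delta > 1) {
    stop("base_beta + delta outside [0, 1]")
  }
  structure(list(n_sites_per_island = n_sites_per_island, groups = groups,
                 base_beta = base_beta, delta = delta,
                 concentration = concentration,
                 overlap_with_counts = overlap_with_counts,
                 seed = as.integer(seed)),
            class = "beta_sim_config")
}

#' Simulate array-style beta values with planted island effects
#'
#' @param cfg A [beta_sim_config()].
#' @param islands Character vector of island feature ids measured on the
#'   array (must include the truth's planted islands).
#' @param truth Truth list from [simulate_counts()]; the islands planted
#'   there (both hyper and hypo ids, hyper only is used) seed the array
#'   effects through `overlap_with_counts`.
#' @return A list of class `beta_matrix`: `betas` (sites x samples),
#'   `site_island` (site -> island id), `group` (per sample),
#'   `planted_islands` (islands carrying the array-side effect).
#' @export
simulate_betas <- function(cfg, islands, truth) {
  stopifnot(inherits(cfg, "beta_sim_config"))
  if (!all(truth$planted_hyper %in% islands)) {
    stop("islands must include all planted island ids")
  }
  set.seed(cfg$seed + 1L)
  n_overlap <- round(cfg$overlap_with_counts * length(truth$planted_hyper))
  planted <- if (n_overlap > 0) {
    sort(sample(truth$planted_hyper, n_overlap))
  } else character(0)

  ni <- length(islands)
  site_island <- rep(islands, each = cfg$n_sites_per_island)
  site_ids <- paste0(site_island, "_s",
                     rep(seq_len(cfg$n_sites_per_island), times = ni))
  grp <- rep(names(cfg$groups), times = cfg$groups)
  samples <- sprintf("%s_%02d", grp,
                     unlist(lapply(cfg$groups, seq_len), use.names = FALSE))
  ns <- length(samples)
  nsite <- length(site_ids)

  mean_mat <- matrix(cfg$base_beta, nsite, ns)
  tumor_cols <- grp == "tumor"
  planted_rows <- site_island %in% planted
  mean_mat[planted_rows, tumor_cols] <- cfg$base_beta + cfg$delta

  a <- mean_mat * cfg$concentration
  b <- (1 - mean_mat) * cfg$concentration
  betas <- matrix(stats::rbeta(nsite * ns, a, b), nsite, ns,
                  dimnames = list(site_ids, samples))
  structure(list(betas = betas,
                 site_island = setNames(site_island, site_ids),
                 group = setNames(grp, samples),
                 planted_islands = planted),
            class = "beta_matrix")
}

#' Simulate spike-in qPCR cycle thresholds
#'
#' Models the qPCR readout of methylated and unmethylated spike-in
#' controls before and after methylation capture. A capture efficiency
#' `e` shifts the enriched Ct by `-log_base(e)` relative to the input
#' (losing material costs cycles); optional Gaussian noise models
#' pipetting/quantification error.
#'
#' @param capture_eff_meth,capture_eff_unmeth Fraction of methylated /
#'   unmethylated control recovered by the capture, in (0, 1].
#' @param ct_input Ct of the unenriched input aliquot.
#' @param efficiency_qpcr Per-cycle amplification base in (1, 2]
#'   (2 = perfect doubling).
#' @param input_dilution Fold-dilution of the unenriched aliquot relative
#'   to the enriched one.
#' @param noise_sd Standard deviation of Ct noise (0 = deterministic).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return A list of class `spikein_ct` with the four Ct values and the
#'   dilution, ready for [recovery()] / [capture_specificity()].
#' @export
simulate_spikein <- function(capture_eff_meth, capture_eff_unmeth,
                             ct_input = 25, efficiency_qpcr = 2,
                             input_dilution = 1, noise_sd = 0, seed = 1L) {
  if (capture_eff_meth <= 0 || capture_eff_unmeth <= 0) {
    stop("zero capture efficiency gives infinite Ct")
  }
  stopifnot(capture_eff_meth <= 1, capture_eff_unmeth <= 1,
            efficiency_qpcr > 1, efficiency_qpcr <= 2)
  set.seed(seed)
  noise <- function() if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
  # the input aliquot is diluted, raising its Ct by log_base(dilution)
  ct_in_obs <- ct_input + log(input_dilution, efficiency_qpcr)
  structure(list(
    ct_meth_input = ct_in_obs + noise(),
    ct_meth_enriched = ct_input - log(capture_eff_meth, efficiency_qpcr) +
      noise(),
    ct_unmeth_input = ct_in_obs + noise(),
    ct_unmeth_enriched = ct_input - log(capture_eff_unmeth, efficiency_qpcr) +
      noise(),
    input_dilution = input_dilution),
    class = "spikein_ct")
}

#' Write simulated inputs to plain-text files
#'
#' Writers for the interchange formats used across the pipeline: a counts
#' TSV (feature_id, class, one column per sample), a sample sheet
#' (sample, group), a beta TSV (site_id, island_id, per-sample betas) and
#' a truth JSON.
#'
#' @param sim Output of [simulate_counts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_count_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- sim$matrix
  counts_path <- file.path(dir, "counts.tsv")
  df <- data.frame(feature_id = rownames(m$counts),
                   class = m$feature_class, m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(data.frame(sample = colnames(m$counts),
                                group = m$group),
                     sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_path, auto_unbox = FALSE,
                       digits = NA)
  invisible(c(counts = counts_path, samples = sheet_path,
              truth = truth_path))
}

#' @rdname write_count_sim
#' @param bm A `beta_matrix` from [simulate_betas()].
#' @export
write_beta_sim <- function(bm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  beta_path <- file.path(dir, "betas.tsv")
  df <- data.frame(site_id = rownames(bm$betas),
                   island_id = unname(bm$site_island), bm$betas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, beta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet_path <- file.path(dir, "beta_samples.tsv")
  utils::write.table(data.frame(sample = colnames(bm$betas),
                                group = unname(bm$group)),
                     sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(betas = beta_path, samples = sheet_path))
}
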