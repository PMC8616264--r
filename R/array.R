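#' Two-group F-test for differentially methylated CpG sites
#'
#' Per CpG site, a one-way two-group linear-model F-test (df1 = 1,
#' pooled equal variance — the square of the two-sample t statistic) on
#' beta values between tumor samples and a comparator group, with the
#' effect reported as `delta_beta = mean(tumor) - mean(comparator)` and
#' BH adjustment over all tested sites. Degenerate sites with zero
#' pooled variance get `p = 1` when the means agree and `p = 0`
#' (flagged) when they differ.
#'
#' @param b A `beta_matrix` (see [simulate_betas()]) or any list with
#'   `betas` (sites x samples), `group` (per sample) and `site_island`.
#' @param comparator Comparator group label (e.g. `"normal"` or
#'   `"pbmc"`); tumor group label fixed by `tumor`.
#' @param tumor Tumor group label (default `"tumor"`).
#' @return Data frame with `site_id`, `island_id`, `delta_beta`,
#'   `fstat`, `pvalue`, `qvalue`, `degenerate`.
#' @export
dmc_test <- function(b, comparator, tumor = "tumor") {
  stopifnot(comparator %in% b$group, tumor %in% b$group)
  g1 <- b$group == tumor
  g2 <- b$group == comparator
  n1 <- sum(g1)
  n2 <- sum(g2)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  x1 <- b$betas[, g1, drop = FALSE]
  x2 <- b$betas[, g2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  delta <- m1 - m2
  tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  fstat <- tstat^2
  p <- stats::pf(fstat, 1, n1 + n2 - 2, lower.tail = FALSE)
  degen <- sp2 == 0
  p[degen & delta == 0] <- 1
  p[degen & delta != 0] <- 0
  fstat[degen] <- ifelse(delta[degen] == 0, 0, Inf)
  data.frame(site_id = rownames(b$betas),
             island_id = unname(b$site_island[rownames(b$betas)]),
             delta_beta = delta, fstat = fstat,
             pvalue = p, qvalue = bh_adjust(p),
             degenerate = degen,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call hypermethylated DMCs
#'
#' One-sided calling: a site is a DMC when `delta_beta > delta_min`
#' (strict, hypermethylation only) and `q < q_max` (strict).
#'
#' @param r Data frame from [dmc_test()].
#' @param delta_min Minimum tumor-minus-comparator mean difference
#'   (default 0.2).
#' @param q_max BH-FDR threshold (default 0.1).
#' @return Logical vector, one flag per row of `r`.
#' @export
call_dmc <- function(r, delta_min = 0.2, q_max = 0.1) {
  !is.na(r$qvalue) & r$delta_beta > delta_min & r$qvalue < q_max
}

#' Collapse DMC sites to their unique CpG islands
#'
#' Drops sites without an island annotation, maps the remainder to their
#' islands and deduplicates, returning a sorted island set.
#'
#' @param dmcs Data frame of called DMCs (rows of [dmc_test()] output
#'   where [call_dmc()] is TRUE), or any data frame with an `island_id`
#'   column (`NA` = not on an island).
#' @return Sorted character vector of unique island region strings.
#' @export
sites_to_island_set <- function(dmcs) {
  ids <- dmcs$island_id
  sort(unique(ids[!is.na(ids)]))
}

#' Island-level beta values
#'
#' Collapses a site-level beta matrix to islands by taking, per island
#' and sample, the unweighted mean of member-site betas. Sites without an
#' island annotation are dropped.
#'
#' @param b A `beta_matrix` (list with `betas`, `site_island`, `group`).
#' @return A `beta_matrix` whose rows are islands (`site_island` maps
#'   each island to itself).
#' @export
collapse_island_betas <- function(b) {
  on_island <- !is.na(b$site_island[rownames(b$betas)])
  if (!any(on_island)) stop("no island-mapped sites to collapse")
  x <- b$betas[on_island, , drop = FALSE]
  isl <- b$site_island[rownames(x)]
  agg <- rowsum(x, group = isl) / as.vector(table(isl)[sort(unique(isl))])
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  structure(list(betas = agg,
                 site_island = setNames(rownames(agg), rownames(agg)),
                 group = b$group),
            class = "beta_matrix")
}

#' Read a beta TSV and sample sheet into a beta_matrix
#'
#' @param beta_path TSV with columns `site_id`, `island_id` and one
#'   column per sample (beta values in `[0, 1]`; empty island_id = not
#'   on an island).
#' @param samples_path TSV with columns `sample`, `group`.
#' @return A `beta_matrix` list.
#' @export
read_beta_matrix <- function(beta_path, samples_path) {
  df <- utils::read.table(beta_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  sheet <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  samples <- setdiff(colnames(df), c("site_id", "island_id"))
  if (!all(samples %in% sheet$sample)) {
    stop("samples missing from sample sheet: ",
         paste(setdiff(samples, sheet$sample), collapse = ", "))
  }
  betas <- as.matrix(df[, samples, drop = FALSE])
  rownames(betas) <- df$site_id
  if (any(betas < 0 | betas > 1, na.rm = TRUE)) {
    stop("beta values outside [0, 1]")
  }
  structure(list(betas = betas,
                 site_island = setNames(df$island_id, df$site_id),
                 group = setNames(sheet$group[match(samples, sheet$sample)],
                                  samples)),
            class = "beta_matrix")
}
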