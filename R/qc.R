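#' Spike-in recovery from qPCR cycle thresholds
#'
#' Fraction of a spike-in control recovered by the capture reaction,
#' estimated from the Ct difference between the unenriched input aliquot
#' and the enriched eluate. Each qPCR cycle is one doubling, so recovery
#' is `100 * 2^(ct_input_corrected - ct_enriched)` where the input Ct is
#' first corrected for its fold-dilution (`- log2(dilution)`). Values can
#' exceed 100% with noisy Ct measurements; they are reported uncapped.
#'
#' @param ct_input Ct of the (diluted) unenriched input.
#' @param ct_enriched Ct of the enriched eluate.
#' @param input_dilution Fold-dilution of the input aliquot (>= 1).
#' @return Recovery in percent.
#' @examples
#' recovery(25, 26) # one cycle lost = 50%
#' @export
recovery <- function(ct_input, ct_enriched, input_dilution = 1) {
  stopifnot(all(input_dilution >= 1))
  100 * 2^((ct_input - log2(input_dilution)) - ct_enriched)
}

#' Specificity of the methylation capture reaction
#'
#' `(1 - recovery_unmeth / recovery_meth) * 100`: the percentage of
#' captured material attributable to methylation-specific binding. Shared
#' dilution factors cancel in the ratio.
#'
#' @param recovery_meth,recovery_unmeth Recoveries (percent) of the
#'   methylated and unmethylated spike-in controls.
#' @return Specificity in percent.
#' @examples
#' capture_specificity(20, 0.1) # 99.5
#' @export
capture_specificity <- function(recovery_meth, recovery_unmeth) {
  if (any(recovery_meth == 0)) {
    stop("recovery of methylated control is 0: specificity undefined")
  }
  (1 - recovery_unmeth / recovery_meth) * 100
}

#' Capture specificity gate
#'
#' Pass/fail decision on the capture reaction: specificity must be at
#' least `threshold` percent (inclusive) before a library proceeds.
#'
#' @param specificity Specificity in percent.
#' @param threshold Minimum acceptable specificity (default 99).
#' @return Logical: TRUE = pass.
#' @export
specificity_gate <- function(specificity, threshold = 99) {
  specificity >= threshold
}

#' QC summary of a spike-in Ct record
#'
#' @param ct A `spikein_ct` (e.g. from [simulate_spikein()]) or any list
#'   with the four Ct fields and `input_dilution`.
#' @param threshold Gate threshold passed to [specificity_gate()].
#' @return List with `recovery_meth`, `recovery_unmeth`, `specificity`
#'   (percent) and `pass` (logical).
#' @export
spikein_qc <- function(ct, threshold = 99) {
  rm_ <- recovery(ct$ct_meth_input, ct$ct_meth_enriched, ct$input_dilution)
  ru_ <- recovery(ct$ct_unmeth_input, ct$ct_unmeth_enriched,
                  ct$input_dilution)
  sp <- capture_specificity(rm_, ru_)
  list(recovery_meth = rm_, recovery_unmeth = ru_, specificity = sp,
       pass = specificity_gate(sp, threshold))
}

#' TPM normalization of a feature count matrix
#'
#' Transcripts-per-kilobase-million scaling: per sample, counts are
#' divided by feature length in kb, then rescaled so each sample column
#' sums to one million.
#'
#' @param m A [feature_count_matrix()].
#' @param lengths Numeric vector of feature lengths in bp, one per row
#'   (all > 0). Defaults to widths parsed from the feature ids.
#' @return Numeric matrix of TPM values, same dimnames as the counts.
#' @export
tpm_normalize <- function(m, lengths = NULL) {
  stopifnot(inherits(m, "feature_count_matrix"))
  if (is.null(lengths)) {
    lengths <- interval_size(parse_region(rownames(m$counts)))
  }
  if (length(lengths) != nrow(m$counts) || any(lengths <= 0)) {
    stop("lengths must be positive, one per feature")
  }
  rate <- m$counts / (lengths / 1000)
  csum <- colSums(rate)
  if (any(csum == 0)) {
    stop("all-zero sample column: ",
         paste(colnames(m$counts)[csum == 0], collapse = ", "))
  }
  sweep(rate, 2, csum / 1e6, "/")
}

#' Per-sample coverage fraction by CpG feature class
#'
#' Percentage of normalized signal falling on each feature class, plus
#' the derived "extended island" share (island + shore + shelf).
#'
#' @param tpm Normalized matrix from [tpm_normalize()].
#' @param classes Character vector of feature classes, one per row.
#' @return Data frame, one row per sample, with columns `island`,
#'   `shore`, `shelf`, `inter` and `extended_island` (percent).
#' @export
class_coverage_fractions <- function(tpm, classes) {
  if (length(classes) != nrow(tpm)) stop("every feature must be classed")
  lv <- c("island", "shore", "shelf", "inter")
  agg <- rowsum(tpm, group = factor(classes, levels = lv))
  pct <- 100 * sweep(agg, 2, colSums(agg), "/")
  pct[is.na(pct)] <- 0
  out <- as.data.frame(t(pct))
  for (cl in setdiff(lv, colnames(out))) out[[cl]] <- 0
  out <- out[, lv]
  out$extended_island <- out$island + out$shore + out$shelf
  out
}

#' Enrichment noise and CpG density at peak
#'
#' Two fragment-level enrichment metrics: `noise`, the mean coverage of
#' fragments containing no CpG divided by the mean coverage of fragments
#' containing at least one CpG; and `cpg_density_at_peak`, the CpG count
#' (bin width 1) of the fragment-density bin with the greatest total
#' coverage (ties resolved to the lower density).
#'
#' @param fragment_cpg_counts Integer vector: CpGs per fragment.
#' @param coverage Numeric vector of per-fragment coverage (same length;
#'   defaults to 1 per fragment, i.e. read counting).
#' @return List with `noise` and `cpg_density_at_peak`.
#' @export
noise_and_peak <- function(fragment_cpg_counts, coverage = NULL) {
  if (!length(fragment_cpg_counts)) stop("no fragments supplied")
  if (is.null(coverage)) coverage <- rep(1, length(fragment_cpg_counts))
  stopifnot(length(coverage) == length(fragment_cpg_counts))
  has_cpg <- fragment_cpg_counts >= 1
  if (!any(has_cpg)) stop("no CpG-containing fragments: noise undefined")
  mean0 <- if (any(!has_cpg)) mean(coverage[!has_cpg]) else 0
  noise <- mean0 / mean(coverage[has_cpg])
  dens <- tapply(coverage, fragment_cpg_counts, sum)
  peak_bins <- as.numeric(names(dens)[dens == max(dens)])
  list(noise = unname(noise), cpg_density_at_peak = min(peak_bins))
}
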