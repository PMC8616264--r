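#' Feature-by-sample count matrix
#'
#' Container for CpG-feature read counts: an integer matrix with feature
#' region strings as row names and sample ids as column names, the
#' feature class of every row, and a per-sample group label.
#'
#' @param counts Integer matrix, features x samples, with dimnames.
#' @param feature_class Character vector of classes (island/shore/shelf/
#'   inter), one per row.
#' @param group Character vector of group labels, one per column.
#' @return An object of class `feature_count_matrix`.
#' @export
feature_count_matrix <- function(counts, feature_class, group) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate feature ids")
  if (length(feature_class) != nrow(counts)) {
    stop("feature_class length != number of rows")
  }
  if (length(group) != ncol(counts)) stop("group length != number of columns")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 feature_class = as.character(feature_class),
                 group = as.character(group)),
            class = "feature_count_matrix")
}

#' @export
print.feature_count_matrix <- function(x, ...) {
  cat("feature_count_matrix:", nrow(x$counts), "features x",
      ncol(x$counts), "samples\n")
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$feature_class)),
                                  table(x$feature_class)), collapse = ", "),
      "\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(table(x$group)),
                                  table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.feature_count_matrix <- function(x) dim(x$counts)

# class priority used to break overlap ties: denser CpG context wins
.class_priority <- c(island = 1, shore = 2, shelf = 3, inter = 4)

#' Count fragments onto CpG features
#'
#' Assigns each sequenced fragment to exactly one feature — the feature
#' with maximal base overlap, ties broken by class priority
#' island > shore > shelf > inter and then by leftmost feature — and
#' tallies per-sample counts. Fragments overlapping nothing (possible
#' only off the annotated partition) are counted to the nearest
#' inter-CpG feature on their chromosome. Single assignment keeps column
#' sums equal to per-sample fragment counts, so downstream class
#' percentages behave as a partition.
#'
#' @param fragments Data frame of fragment intervals with columns
#'   `chrom`, `start`, `end`, `sample` (1-based inclusive).
#' @param features Feature annotation from [derive_feature_classes()].
#' @param group Named character vector mapping sample id to group label;
#'   if NULL, all samples are labelled `"unknown"`.
#' @return A [feature_count_matrix()] over all annotation features
#'   (samples in sorted order).
#' @export
count_fragments <- function(fragments, features, group = NULL) {
  samples <- sort(unique(fragments$sample))
  frag_gr <- GenomicRanges::GRanges(
    fragments$chrom,
    IRanges::IRanges(fragments$start, fragments$end))
  feat_gr <- GenomicRanges::GRanges(
    features$chrom,
    IRanges::IRanges(features$start, features$end))
  hits <- GenomicRanges::findOverlaps(frag_gr, feat_gr)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(frag_gr[qh],
                                                       feat_gr[sh]))
  # per fragment: max overlap, then class priority, then leftmost
  ord <- order(qh, -ov, .class_priority[features$class[sh]],
               features$start[sh])
  keep <- !duplicated(qh[ord])
  assigned <- rep(NA_integer_, nrow(fragments))
  assigned[qh[ord][keep]] <- sh[ord][keep]

  if (anyNA(assigned)) {
    miss <- which(is.na(assigned))
    for (i in miss) {
      cand <- which(features$chrom == fragments$chrom[i] &
                      features$class == "inter")
      if (!length(cand)) {
        stop("fragment on unannotated chromosome: ", fragments$chrom[i])
      }
      d <- pmax(features$start[cand] - fragments$end[i],
                fragments$start[i] - features$end[cand], 0)
      assigned[i] <- cand[which.min(d)]
    }
  }
  counts <- matrix(0L, nrow(features), length(samples),
                   dimnames = list(features$feature_id, samples))
  tab <- table(factor(assigned, levels = seq_len(nrow(features))),
               factor(fragments$sample, levels = samples))
  counts[] <- as.integer(tab)
  if (is.null(group)) group <- setNames(rep("unknown", length(samples)),
                                        samples)
  feature_count_matrix(counts, features$class, unname(group[samples]))
}

#' Filter the count matrix before differential analysis
#'
#' Drops every inter-CpG row and every row whose counts are zero in all
#' samples, preserving the order of the remaining rows. Idempotent.
#'
#' @param m A [feature_count_matrix()].
#' @return The filtered `feature_count_matrix`.
#' @export
filter_matrix <- function(m) {
  stopifnot(inherits(m, "feature_count_matrix"))
  keep <- m$feature_class != "inter" & rowSums(m$counts) > 0
  if (!any(keep)) {
    stop("filtering removed every row: degenerate input matrix")
  }
  feature_count_matrix(m$counts[keep, , drop = FALSE],
                       m$feature_class[keep], m$group)
}

#' Restrict a count matrix to CpG island rows
#'
#' @param m A [feature_count_matrix()].
#' @return The island-only `feature_count_matrix`.
#' @export
subset_islands <- function(m) {
  stopifnot(inherits(m, "feature_count_matrix"))
  keep <- m$feature_class == "island"
  feature_count_matrix(m$counts[keep, , drop = FALSE],
                       m$feature_class[keep], m$group)
}

#' Read a counts TSV and sample sheet into a feature_count_matrix
#'
#' @param counts_path TSV with columns `feature_id`, `class`, then one
#'   column per sample.
#' @param samples_path TSV with columns `sample`, `group`.
#' @return A [feature_count_matrix()].
#' @export
read_count_matrix <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  sheet <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  samples <- setdiff(colnames(df), c("feature_id", "class"))
  if (!all(samples %in% sheet$sample)) {
    stop("samples missing from sample sheet: ",
         paste(setdiff(samples, sheet$sample), collapse = ", "))
  }
  counts <- as.matrix(df[, samples, drop = FALSE])
  rownames(counts) <- df$feature_id
  feature_count_matrix(counts, df$class,
                       sheet$group[match(samples, sheet$sample)])
}
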