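#' Tumor-derived island set
#'
#' Three-way intersection of the plasma case-vs-control DMCGIs with the
#' tumor-vs-normal and tumor-vs-PBMC array-derived DMCGI sets. Islands
#' surviving all three comparisons are attributed to tumor-derived
#' methylation rather than to cohort artefacts or clonal hematopoiesis.
#' Membership is by exact island region string (the sets are assumed
#' harmonized to one island annotation).
#'
#' @param plasma,tumor_vs_normal,tumor_vs_pbmc Character vectors of
#'   island region strings.
#' @return Sorted character vector: the triple intersection.
#' @export
tumor_derived <- function(plasma, tumor_vs_normal, tumor_vs_pbmc) {
  sort(intersect(intersect(unique(plasma), unique(tumor_vs_normal)),
                 unique(tumor_vs_pbmc)))
}

#' Overlap percentage, one decimal, half-up
#'
#' `100 * n_overlap / n_total` rounded half-up to one decimal place
#' (so 84.45 reports as 84.5, unlike banker's rounding).
#'
#' @param n_overlap,n_total Counts, `0 <= n_overlap <= n_total`,
#'   `n_total > 0`.
#' @return Percentage with one decimal.
#' @examples
#' overlap_percent(1486, 1759) # 84.5
#' @export
overlap_percent <- function(n_overlap, n_total) {
  if (any(n_total == 0)) stop("n_total must be positive")
  stopifnot(all(n_overlap >= 0), all(n_overlap <= n_total))
  floor(1000 * n_overlap / n_total + 0.5) / 10
}

#' Three-set Venn decomposition
#'
#' Exact counts of the seven regions of a three-set Venn diagram, plus
#' set sizes and the union size.
#'
#' @param a,b,c Character vectors (duplicates ignored).
#' @param labels Names of the three sets.
#' @return List of class `venn3`: `regions` (named counts `a_only`,
#'   `b_only`, `c_only`, `ab_only`, `ac_only`, `bc_only`, `abc`),
#'   `sizes`, `union_size`, and `specific_total` (sum of the three
#'   single-set regions).
#' @export
venn3 <- function(a, b, c, labels = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  u <- union(union(a, b), c)
  ina <- u %in% a
  inb <- u %in% b
  inc <- u %in% c
  regions <- c(
    a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab_only = sum(ina & inb & !inc),
    ac_only = sum(ina & !inb & inc),
    bc_only = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
  structure(list(regions = regions,
                 sizes = setNames(c(length(a), length(b), length(c)),
                                  labels),
                 union_size = length(u),
                 specific_total = sum(regions[c("a_only", "b_only",
                                                "c_only")]),
                 labels = labels),
            class = "venn3")
}

#' @export
print.venn3 <- function(x, ...) {
  cat("3-set Venn decomposition (", paste(x$labels, collapse = " / "),
      ")\n", sep = "")
  print(x$regions)
  cat("union:", x$union_size,
      " set-specific total:", x$specific_total, "\n")
  invisible(x)
}

#' Cancer-type-specific island sets
#'
#' Members of exactly one of the three sets, per label.
#'
#' @param a,b,c Character vectors of island ids.
#' @param labels Names for the three cohorts.
#' @return Named list of sorted character vectors, one per label, plus
#'   attribute `total` (sum of the three sizes).
#' @export
type_specific <- function(a, b, c, labels = c("a", "b", "c")) {
  a <- unique(a); b <- unique(b); c <- unique(c)
  out <- list(sort(setdiff(a, union(b, c))),
              sort(setdiff(b, union(a, c))),
              sort(setdiff(c, union(a, b))))
  names(out) <- labels
  attr(out, "total") <- sum(lengths(out))
  out
}

#' Read / write island-set text files (one region string per line)
#'
#' @param path File path.
#' @return `read_island_set`: sorted character vector.
#' @export
read_island_set <- function(path) {
  sort(unique(readLines(path, warn = FALSE)))
}

#' @rdname read_island_set
#' @param members Character vector of island region strings.
#' @export
write_island_set <- function(members, path) {
  writeLines(sort(unique(members)), path)
  invisible(path)
}
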