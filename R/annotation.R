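#' Parse a genomic region string
#'
#' Parses region identifiers of the form `"chrom:start-end"` into a
#' one-row data frame. Coordinates are 1-based and inclusive on both ends,
#' the convention under which the width of `chrom:s-e` is `e - s + 1`.
#'
#' @param text Character vector of region strings, e.g.
#'   `"chr2:29337984-29338909"`.
#' @return A data.frame with columns `chrom` (character), `start`, `end`
#'   (integer-valued numeric), one row per input string.
#' @examples
#' parse_region("chr2:29337984-29338909")
#' @export
parse_region <- function(text) {
  if (!is.character(text) || length(text) < 1L) {
    stop("'text' must be a non-empty character vector")
  }
  ok <- grepl("^[A-Za-z0-9_.]+:[0-9]+-[0-9]+$", text)
  if (any(!ok)) {
    stop("malformed region string: '", text[!ok][1L], "'")
  }
  chrom <- sub(":.*$", "", text)
  rest <- sub("^[^:]+:", "", text)
  start <- as.numeric(sub("-.*$", "", rest))
  end <- as.numeric(sub("^.*-", "", rest))
  if (any(start < 1)) {
    stop("start coordinate below 1 in '", text[start < 1][1L], "'")
  }
  if (any(end < start)) {
    stop("inverted bounds (start > end) in '", text[end < start][1L], "'")
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Format intervals as region strings
#'
#' Inverse of [parse_region()]: `chrom:start-end` with 1-based inclusive
#' coordinates.
#'
#' @param iv Data frame with columns `chrom`, `start`, `end`.
#' @return Character vector of region strings.
#' @export
region_string <- function(iv) {
  sprintf("%s:%d-%d", iv$chrom, as.integer(iv$start), as.integer(iv$end))
}

#' Interval size in base pairs
#'
#' @param iv Data frame with `start` and `end` columns (1-based inclusive).
#' @return Numeric vector of widths, `end - start + 1`.
#' @examples
#' interval_size(parse_region("chr2:29337984-29338909")) # 926
#' @export
interval_size <- function(iv) {
  stopifnot(all(iv$end >= iv$start), all(iv$start >= 1))
  iv$end - iv$start + 1
}

#' Derive CpG feature classes from island coordinates
#'
#' Expands a set of non-overlapping CpG islands into the standard
#' island / shore / shelf / inter-CpG partition of each chromosome:
#' shores are the 2 kb flanks immediately adjacent to an island, shelves
#' the next 2 kb band (2-4 kb from the island edge), and everything
#' further away is inter-CpG. Where the flanks of two nearby islands would
#' collide, each base is assigned to the nearer island edge, i.e. the gap
#' is split at its midpoint (ties go to the upstream island). The output
#' partitions every chromosome in `chrom_sizes`: classes are mutually
#' disjoint and jointly exhaustive.
#'
#' @param islands Data frame of island intervals (`chrom`, `start`, `end`),
#'   1-based inclusive, non-overlapping within each chromosome.
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp,
#'   covering every chromosome that carries an island. Chromosomes without
#'   islands come out entirely inter-CpG.
#' @param shore_bp,shelf_bp Widths of the shore and shelf bands (default
#'   2000 bp each, the UCSC convention).
#' @return A data.frame of features with columns `chrom`, `start`, `end`,
#'   `class` (one of `"island"`, `"shore"`, `"shelf"`, `"inter"`) and
#'   `feature_id` (the region string), sorted by chromosome then start.
#' @export
derive_feature_classes <- function(islands, chrom_sizes,
                                   shore_bp = 2000, shelf_bp = 2000) {
  stopifnot(is.numeric(chrom_sizes), !is.null(names(chrom_sizes)))
  if (nrow(islands) > 0) {
    missing_chr <- setdiff(unique(islands$chrom), names(chrom_sizes))
    if (length(missing_chr)) {
      stop("no chromosome size for: ", paste(missing_chr, collapse = ", "))
    }
    if (any(islands$start < 1) ||
        any(islands$end > chrom_sizes[islands$chrom])) {
      stop("island outside chromosome bounds")
    }
  }
  flank_bp <- shore_bp + shelf_bp
  out <- vector("list", length(chrom_sizes))
  names(out) <- names(chrom_sizes)
  for (chr in names(chrom_sizes)) {
    L <- chrom_sizes[[chr]]
    isl <- islands[islands$chrom == chr, , drop = FALSE]
    isl <- isl[order(isl$start), , drop = FALSE]
    if (nrow(isl) > 1 && any(isl$start[-1] <= isl$end[-nrow(isl)])) {
      stop("overlapping islands on ", chr)
    }
    segs <- list()
    add <- function(start, end, class) {
      if (end >= start) segs[[length(segs) + 1L]] <<- c(start, end, class)
    }
    n <- nrow(isl)
    if (n == 0) {
      add(1, L, "inter")
    } else {
      # walk gaps: sentinel edges at 0 and L+1 with no flank claim
      bounds_lo <- c(0, isl$end)        # left edge of each gap owner
      bounds_hi <- c(isl$start, L + 1)  # right edge of each gap
      for (g in seq_len(n + 1L)) {
        le <- bounds_lo[g]  # island end to the left (0 if chrom start)
        rs <- bounds_hi[g]  # island start to the right (L+1 if chrom end)
        lo <- le + 1
        hi <- rs - 1
        if (hi < lo) next
        if (le == 0 && rs == L + 1) {   # unreachable when n > 0
          add(lo, hi, "inter")
          next
        }
        if (le == 0) {
          # chromosome start: only the right island claims, up to flank_bp
          claim_r_lo <- max(lo, rs - flank_bp)
          add(lo, claim_r_lo - 1, "inter")
          add(claim_r_lo, max(claim_r_lo - 1, rs - shore_bp - 1), "shelf")
          add(max(claim_r_lo, rs - shore_bp), rs - 1, "shore")
        } else if (rs == L + 1) {
          claim_l_hi <- min(hi, le + flank_bp)
          add(lo, min(claim_l_hi, le + shore_bp), "shore")
          add(le + shore_bp + 1, claim_l_hi, "shelf")
          add(claim_l_hi + 1, hi, "inter")
        } else {
          # interior gap: split at midpoint, ties to the upstream island
          mid <- floor((le + rs) / 2)
          claim_l_hi <- min(mid, le + flank_bp)
          claim_r_lo <- max(mid + 1, rs - flank_bp)
          add(lo, min(claim_l_hi, le + shore_bp), "shore")
          add(le + shore_bp + 1, claim_l_hi, "shelf")
          add(claim_l_hi + 1, claim_r_lo - 1, "inter")
          add(claim_r_lo, max(claim_r_lo - 1, rs - shore_bp - 1), "shelf")
          add(max(claim_r_lo, rs - shore_bp), rs - 1, "shore")
        }
      }
      for (i in seq_len(n)) add(isl$start[i], isl$end[i], "island")
    }
    df <- do.call(rbind, lapply(segs, function(s) {
      data.frame(chrom = chr, start = as.numeric(s[1]), end = as.numeric(s[2]),
                 class = s[3], stringsAsFactors = FALSE)
    }))
    out[[chr]] <- df[order(df$start), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$feature_id <- region_string(res)
  res
}

#' Genome fraction covered by each CpG feature class
#'
#' @param features Feature data frame from [derive_feature_classes()]
#'   (must partition the genome given by `chrom_sizes`).
#' @param chrom_sizes Named numeric vector of chromosome lengths.
#' @return Named numeric vector of percentages (island, shore, shelf,
#'   inter), summing to 100.
#' @export
genome_fraction_by_class <- function(features, chrom_sizes) {
  if (is.null(features) || nrow(features) == 0) {
    stop("empty feature list does not partition the genome")
  }
  total <- sum(chrom_sizes)
  widths <- interval_size(features)
  if (!isTRUE(all.equal(sum(widths), total))) {
    stop("features do not partition the genome: covered ",
         sum(widths), " of ", total, " bp")
  }
  # disjointness: per chromosome, sorted intervals must not overlap
  for (chr in unique(features$chrom)) {
    f <- features[features$chrom == chr, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) > 1 && any(f$start[-1] <= f$end[-nrow(f)])) {
      stop("overlapping features on ", chr)
    }
  }
  pct <- 100 * tapply(widths, features$class, sum) / total
  lv <- c("island", "shore", "shelf", "inter")
  out <- setNames(rep(0, length(lv)), lv)
  out[names(pct)] <- pct
  out
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open on disk; intervals are returned 1-based
#' inclusive. A fourth column, when present, is kept as `name`.
#'
#' @param path Path to a BED3/BED4 file (plain text, tab-separated).
#' @return Data frame with `chrom`, `start`, `end` (+ `name` for BED4).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = df[[2]] + 1, end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$name <- as.character(df[[4]])
  out
}

#' Write intervals to a BED file
#'
#' Converts from in-memory 1-based inclusive coordinates to on-disk
#' 0-based half-open BED.
#'
#' @param iv Data frame with `chrom`, `start`, `end` and optionally a
#'   name column given by `name_col` (written as BED column 4).
#' @param path Output path.
#' @param name_col Optional column name to write as the BED name field.
#' @export
write_bed <- function(iv, path, name_col = NULL) {
  out <- data.frame(iv$chrom, as.integer(iv$start - 1), as.integer(iv$end))
  if (!is.null(name_col)) out[[4]] <- iv[[name_col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with columns chromosome name and length in bp.
#' @return Named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
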