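# Per-base feature-class oracle: label every base of a chromosome by its
# distance to the nearest island edge (ties to the upstream island).
oracle_classes <- function(islands, chrom_sizes, shore = 2000,
                           shelf = 2000) {
  out <- list()
  for (chr in names(chrom_sizes)) {
    L <- chrom_sizes[[chr]]
    lab <- rep("inter", L)
    isl <- islands[islands$chrom == chr, , drop = FALSE]
    if (nrow(isl)) {
      pos <- seq_len(L)
      dmat <- sapply(seq_len(nrow(isl)), function(i)
        pmax(isl$start[i] - pos, pos - isl$end[i], 0))
      dmat <- matrix(dmat, nrow = L)
      d <- apply(dmat, 1, min)
      lab[d == 0] <- "island"
      lab[d > 0 & d <= shore] <- "shore"
      lab[d > shore & d <= shore + shelf] <- "shelf"
    }
    out[[chr]] <- lab
  }
  out
}

# Expand interval features to a per-base label vector (errors on overlap
# or gap, so it doubles as a partition check).
expand_features <- function(feat, chrom_sizes) {
  out <- list()
  for (chr in names(chrom_sizes)) {
    lab <- rep(NA_character_, chrom_sizes[[chr]])
    f <- feat[feat$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      idx <- f$start[i]:f$end[i]
      if (any(!is.na(lab[idx]))) stop("overlapping features")
      lab[idx] <- f$class[i]
    }
    if (anyNA(lab)) stop("uncovered bases")
    out[[chr]] <- lab
  }
  out
}

# Random non-overlapping islands on one toy chromosome.
random_islands <- function(L, n_max = 5) {
  n <- sample(seq_len(n_max), 1)
  s <- sort(sample(seq(1, L - 600), n))
  isl <- data.frame(chrom = "chr1", start = s,
                    end = pmin(s + sample(100:1500, n, replace = TRUE), L))
  # greedy left-to-right filter so the kept islands never overlap
  keep <- 1L
  for (i in seq_len(nrow(isl))[-1]) {
    if (isl$start[i] > isl$end[keep[length(keep)]]) keep <- c(keep, i)
  }
  isl[keep, , drop = FALSE]
}

# Minimal island-only feature table (no flanks), enough for simulation
# and differential testing.
make_islands <- function(n, width = 1000, gap = 9000) {
  start <- (seq_len(n) - 1) * (width + gap) + 1
  f <- data.frame(chrom = "chr1", start = start, end = start + width - 1,
                  class = "island", stringsAsFactors = FALSE)
  f$feature_id <- sprintf("%s:%d-%d", f$chrom, f$start, f$end)
  f
}

# Brute-force BH step-up: q_(i) = min over j >= i of p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force AUC: fraction of (pos, neg) pairs ranked correctly, ties 1/2.
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Gaussian classifier dataset: 3 informative features among noise.
make_clf_data <- function(seed, n = 160, p = 100, effect = 1.5,
                          null = FALSE) {
  set.seed(seed)
  y <- rep(c("case", "control"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  planted <- c("f001", "f002", "f003")
  if (!null) X[y == "case", planted] <- X[y == "case", planted] + effect
  list(X = X, y = y, planted = planted)
}
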