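# brute-force fragment assignment: per-base overlap with every feature,
# max overlap, class priority, leftmost
assign_oracle <- function(frag, features) {
  prio <- c(island = 1, shore = 2, shelf = 3, inter = 4)
  best <- NA_integer_
  best_key <- c(-Inf, Inf, Inf)
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != frag$chrom) next
    ov <- length(intersect(seq(frag$start, frag$end),
                           seq(features$start[i], features$end[i])))
    key <- c(ov, prio[features$class[i]], features$start[i])
    if (ov > 0 &&
        (key[1] > best_key[1] ||
         (key[1] == best_key[1] && key[2] < best_key[2]) ||
         (key[1] == best_key[1] && key[2] == best_key[2] &&
          key[3] < best_key[3]))) {
      best <- i
      best_key <- key
    }
  }
  best
}

toy_features <- function() {
  derive_feature_classes(
    data.frame(chrom = "chr1", start = c(3001, 6001), end = c(4000, 6500)),
    c(chr1 = 10000), shore_bp = 500, shelf_bp = 500)
}

test_that("fragments land on the feature with maximal overlap", {
  feats <- toy_features()
  frags <- data.frame(
    chrom = "chr1",
    start = c(3100, 3950, 3971, 1),
    end = c(3160, 4070, 4090, 60),
    sample = "s1", stringsAsFactors = FALSE)
  # fully inside island; two boundary-straddlers whose larger side is
  # the downstream shore; far upstream inter
  m <- count_fragments(frags, feats)
  expect_equal(unname(m$counts["chr1:3001-4000", "s1"]), 1)  # island
  expect_equal(unname(m$counts["chr1:4001-4500", "s1"]), 2)  # shore
  expect_equal(unname(m$counts["chr1:1-2000", "s1"]), 1)     # inter
  expect_equal(sum(m$counts[, "s1"]), 4)
})

test_that("even splits go to the higher-priority class", {
  feats <- toy_features()
  # 60 bp split 30/30 across the island/shore boundary at 4000|4001
  frag <- data.frame(chrom = "chr1", start = 3971, end = 4030,
                     sample = "s1")
  m <- count_fragments(frag, feats)
  expect_equal(unname(m$counts["chr1:3001-4000", "s1"]), 1)
})

test_that("fragment assignment matches the brute-force oracle", {
  set.seed(202)
  for (rep in 1:30) {
    L <- 10000
    isl <- random_islands(L, n_max = 3)
    feats <- derive_feature_classes(isl, c(chr1 = L), shore_bp = 500,
                                    shelf_bp = 500)
    n <- 40
    start <- sample(seq_len(L - 100), n)
    frags <- data.frame(chrom = "chr1", start = start,
                        end = start + sample(20:99, n, replace = TRUE),
                        sample = sample(c("s1", "s2"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
    m <- count_fragments(frags, feats)
    want <- matrix(0L, nrow(feats), 2,
                   dimnames = list(feats$feature_id, c("s1", "s2")))
    for (i in seq_len(n)) {
      j <- assign_oracle(frags[i, ], feats)
      want[j, frags$sample[i]] <- want[j, frags$sample[i]] + 1L
    }
    expect_identical(m$counts, want)
    # each fragment counted exactly once
    expect_equal(unname(colSums(m$counts)),
                 unname(as.vector(table(frags$sample))))
  }
})

test_that("row filtering drops inter rows and all-zero rows, idempotently", {
  counts <- matrix(c(5, 3, 0, 0, 2, 7), 3, 2, byrow = TRUE,
                   dimnames = list(c("chr1:1-10", "chr1:21-30",
                                     "chr1:41-50"), c("s1", "s2")))
  m <- feature_count_matrix(counts, c("inter", "island", "shore"),
                            c("a", "b"))
  f <- filter_matrix(m)
  expect_equal(rownames(f$counts), "chr1:41-50")
  expect_identical(filter_matrix(f)$counts, f$counts)

  # no inter rows, no zero rows: identity
  m2 <- feature_count_matrix(counts[c(1, 3), ] + 1,
                             c("island", "shore"), c("a", "b"))
  expect_identical(filter_matrix(m2)$counts, m2$counts)

  # all rows removable -> degenerate-input error
  m3 <- feature_count_matrix(
    matrix(0L, 1, 2, dimnames = list("chr1:1-5", c("s1", "s2"))),
    "island", c("a", "b"))
  expect_error(filter_matrix(m3), "degenerate")
})

test_that("island subsetting keeps island rows and sample columns intact", {
  counts <- matrix(1:10, 5, 2,
                   dimnames = list(sprintf("chr1:%d-%d", 1:5 * 10,
                                           1:5 * 10 + 5),
                                   c("s1", "s2")))
  cls <- c("island", "shore", "island", "shelf", "island")
  m <- feature_count_matrix(counts, cls, c("a", "b"))
  sub <- subset_islands(m)
  expect_equal(nrow(sub$counts), 3)
  expect_identical(sub$counts, counts[cls == "island", ])
  expect_identical(subset_islands(sub)$counts, sub$counts)
  # 5 islands, 2 all-zero -> filter then subset leaves 3
  counts0 <- counts
  counts0[c(2, 4), ] <- 5L
  counts0[c(1, 3), ] <- 0L
  m0 <- feature_count_matrix(counts0, rep("island", 5), c("a", "b"))
  expect_equal(nrow(subset_islands(filter_matrix(m0))$counts), 3)
})

test_that("count matrix construction validates its invariants", {
  cm <- matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(feature_count_matrix(cm - 2, c("a", "b"), c("x", "y")),
               "non-negative")
  expect_error(feature_count_matrix(cm, "a", c("x", "y")), "length")
  expect_error(
    feature_count_matrix(
      matrix(1:4, 2, 2, dimnames = list(c("f1", "f1"), c("s1", "s2"))),
      c("a", "b"), c("x", "y")),
    "duplicate")
})
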