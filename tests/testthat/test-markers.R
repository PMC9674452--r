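test_that("error rate counts mismatches over comparable scores", {
  # identical replicates
  expect_equal(estimate_error_rate(c(0, 1, 1, 0), c(0, 1, 1, 0))$e, 0)
  # 1 mismatch over 4 scores
  er <- estimate_error_rate(c(0, 1, 1, 0), c(0, 1, 0, 0))
  expect_equal(er$e, 0.25)
  expect_equal(er$n_compared, 4L)
  expect_equal(er$n_mismatch, 1L)
  # missing scores are not comparable
  er2 <- estimate_error_rate(c(0, NA, 1, 0), c(0, 1, NA, 1))
  expect_equal(er2$n_compared, 2L)
  expect_equal(er2$e, 0.5)
  # a replicate campaign with 183 mismatches over 2771 compared scores
  a <- rep(0L, 2771)
  b <- a; b[seq_len(183)] <- 1L
  er3 <- estimate_error_rate(list(list(a, b)))
  expect_equal(er3$e, 183 / 2771)
  expect_equal(round(er3$e, 3), 0.066)
  # no comparable scores errors
  expect_error(estimate_error_rate(c(NA, NA), c(1, NA)), "comparable")
  expect_error(estimate_error_rate(c(0, 1), c(1, 0, 1)), "equal length")
})

test_that("replicate coverage and clone threshold reproduce the worked arithmetic", {
  expect_equal(round(100 * replicate_coverage(2771, 250, 54), 1), 20.5)
  thr <- clone_threshold(0.066, 54)
  expect_equal(round(thr$raw, 1), 3.6)
  expect_identical(thr$threshold, 4L)
  expect_equal(clone_threshold(0, 54), list(raw = 0, threshold = 0L))
  expect_equal(clone_threshold(0.10, 20), list(raw = 2, threshold = 2L))
  # half-up rounding, not banker's
  expect_identical(clone_threshold(0.05, 50)$threshold, 3L)
})

# Helper: marker matrix from a 0/1 row list.
mm_from_rows <- function(rows, pop = NULL, pos = NULL) {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  marker_matrix(m, pop %||% rep("A", nrow(m)), pos)
}

test_that("clone detection joins pairs at or below the threshold via components", {
  L <- 52
  base <- rep(0L, L)
  flip <- function(v, idx) { v[idx] <- 1L - v[idx]; v }
  far <- flip(base, 1:30)
  rows <- list(
    A = base,
    B = flip(base, 1:3),          # A-B differ at 3
    C = flip(flip(base, 1:3), 4:7),  # B-C differ at 4, A-C at 7
    D = far,
    E = flip(far, 31:40),         # D-E differ at 10
    F = flip(base, 20:45)         # far from everything
  )
  m <- mm_from_rows(rows)
  call <- detect_clones(m, 4)
  expect_equal(
    canon_partition(call$groups),
    canon_partition(list(c("A", "B", "C"), "D", "E", "F"))
  )
  # matches the brute-force union-find oracle
  expect_equal(canon_partition(call$groups),
               canon_partition(oracle_clone_groups(m$scores, 4)))
  # identical rows at threshold 0 group together; 5 mismatches at threshold 4 do not
  m2 <- mm_from_rows(list(X = base, Y = base, Z = flip(base, 1:5)))
  expect_equal(canon_partition(detect_clones(m2, 0)$groups),
               canon_partition(list(c("X", "Y"), "Z")))
  expect_equal(detect_clones(m2, 4)$n_groups, 2L)
})

test_that("clone partition agrees with the brute-force oracle on random matrices", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12; L <- 20
    scores <- matrix(rbinom(n * L, 1, 0.5), n, L,
                     dimnames = list(paste0("i", 1:n), paste0("L", 1:L)))
    scores[sample(length(scores), 15)] <- NA
    keep <- colSums(!is.na(scores)) > 0
    scores <- scores[, keep, drop = FALSE]
    m <- marker_matrix(scores, rep("A", n))
    thr <- sample(0:6, 1)
    expect_equal(canon_partition(detect_clones(m, thr)$groups),
                 canon_partition(oracle_clone_groups(scores, thr)))
    # permutation of individuals changes labels only, not the partition
    perm <- sample(n)
    mp <- marker_matrix(scores[perm, ], rep("A", n))
    expect_equal(canon_partition(detect_clones(mp, thr)$groups),
                 canon_partition(detect_clones(m, thr)$groups))
  }
})

test_that("deduplication keeps one individual per group, deterministically", {
  set.seed(3)
  L <- 40
  base <- matrix(rbinom(250 * L, 1, 0.5), 250, L,
                 dimnames = list(sprintf("i%03d", 1:250), paste0("L", 1:L)))
  # 3 exact clone pairs
  base[2, ] <- base[1, ]; base[50, ] <- base[49, ]; base[200, ] <- base[199, ]
  m <- marker_matrix(base, rep(c("A", "B"), each = 125))
  call <- detect_clones(m, 0)
  expect_equal(call$n_groups, 247L)
  d1 <- deduplicate(m, call, seed = 17)
  expect_equal(nrow(d1$scores), 247L)
  d2 <- deduplicate(m, call, seed = 17)
  expect_identical(rownames(d1$scores), rownames(d2$scores))
  # every seed retains exactly |groups| individuals
  for (s in 1:4)
    expect_equal(nrow(deduplicate(m, call, s)$scores), 247L)
  # no multi-member groups: output identical to input
  m0 <- marker_matrix(base[5:10, ], rep("A", 6))
  call0 <- detect_clones(m0, 0)
  expect_identical(deduplicate(m0, call0, 1)$scores, m0$scores)
})

test_that("transect distances are reported for within-population clone pairs", {
  base <- rep(0L, 30)
  m <- mm_from_rows(list(A = base, B = base, C = rep(1L, 30)),
                    pop = c("P1", "P1", "P1"), pos = c(1.0, 1.4, 9))
  call <- detect_clones(m, 0)
  expect_equal(call$pair_distances_m, 0.4, tolerance = 1e-12)
})

test_that("locus exclusion preserves order and validates names", {
  set.seed(5)
  scores <- matrix(rbinom(6 * 54, 1, 0.5), 6, 54,
                   dimnames = list(paste0("i", 1:6),
                                   c(paste0("A", 1:52), "C02F", "C02G")))
  m <- marker_matrix(scores, rep("A", 6))
  m2 <- drop_loci(m, c("C02F", "C02G"))
  expect_equal(ncol(m2$scores), 52L)
  expect_identical(colnames(m2$scores), paste0("A", 1:52))
  expect_identical(drop_loci(m, character(0)), m)
  expect_error(drop_loci(m, "nope"), "unknown locus")
  expect_error(drop_loci(m, colnames(scores)), "all loci")
})

test_that("marker files round-trip bit-exactly in both dialects", {
  set.seed(9)
  scores <- matrix(rbinom(8 * 10, 1, 0.4), 8, 10,
                   dimnames = list(sprintf("ind%02d", 1:8), paste0("L", 1:10)))
  scores[c(3, 17)] <- NA
  m <- marker_matrix(scores, rep(c("north", "south"), each = 4),
                     position = seq(0, 14, 2))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_marker_matrix(m, csv, "csv")
  m_csv <- read_marker_matrix(csv, "csv")
  expect_identical(m_csv$scores, m$scores)
  expect_identical(m_csv$population, m$population)
  expect_equal(m_csv$position, m$position)
  gx <- withr::local_tempfile(fileext = ".txt")
  write_marker_matrix(m, gx, "genalex")
  m_gx <- read_marker_matrix(gx, "genalex")
  expect_identical(m_gx$scores, m$scores)
  expect_identical(m_gx$population, m$population)
})

test_that("malformed marker files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,population_id,L1,L2",
               "i1,A,0,1", "i2,A,0,2"), f)
  expect_error(read_marker_matrix(f, "csv"), "unknown score symbol")
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("2,2,1,2", "t,,A", "sample,pop,L1,L2",
               "i1,A,0,1", "i2,A,0"), g)
  expect_error(read_marker_matrix(g, "genalex"), "row 2")
  expect_error(read_marker_matrix("does-not-exist.csv"), "not found")
})
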