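test_that("informative filter keeps exactly sites with >= min_pairs complete pairs", {
  # site 1: observed in both members of exactly 5 pairs -> retained;
  # site 2: 5 tumors observed but matched normals missing -> dropped
  vals <- matrix(runif(2 * 12), 2)
  vals[1, c(6, 6 + 6)] <- NA            # pair 6 incomplete -> 5 complete
  vals[2, 7:12] <- NA                   # all normals missing
  em <- toy_matrix(vals)
  kept <- informative_filter(em, min_pairs = 5)
  expect_identical(kept$sites$site_id, em$sites$site_id[1])
  expect_identical(kept$samples, em$samples)  # sample set unchanged

  # brute-force pair-counting oracle on a random 50-site matrix
  set.seed(11)
  v <- matrix(runif(50 * 16), 50)
  v[runif(length(v)) < 0.4] <- NA
  em2 <- toy_matrix(v)
  kept2 <- informative_filter(em2, min_pairs = 5)
  brute <- vapply(seq_len(50), function(i) {
    sum(vapply(1:8, function(p) {
      !is.na(v[i, p]) && !is.na(v[i, p + 8])
    }, TRUE)) >= 5
  }, TRUE)
  expect_identical(kept2$sites$site_id, em2$sites$site_id[brute])

  em_nopair <- editing_matrix(
    matrix(0.5, 1, 2, dimnames = list(NULL, c("a", "b"))),
    genomic_sites("chr1", 1), c("tumor", "normal"))
  expect_error(informative_filter(em_nopair), "pairing metadata")
})

test_that("rank-sum test: complete separation of 3 vs 3 gives exact p = 0.1", {
  res <- rank_sum_test(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$statistic, 9)  # all 3 tumor values above all normals
})

test_that("rank-sum test handles degenerate groups per contract", {
  # identical constant groups: no rank information, p = 1
  expect_equal(rank_sum_test(c(0.2, 0.2), c(0.2, 0.2))$p_value, 1)
  # empty group: untestable, p missing (never silently 1)
  expect_true(is.na(rank_sum_test(numeric(), c(0.1))$p_value))
  expect_true(is.na(rank_sum_test(c(NA_real_), c(0.1, 0.2))$p_value))
})

test_that("exact branch matches full-enumeration oracle for small groups", {
  set.seed(23)
  for (rep in 1:40) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(seq(0.01, 0.99, by = 0.01), m + n)  # distinct -> no ties
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    res <- rank_sum_test(x, y)
    orc <- enum_ranksum_p(x, y)
    expect_equal(res$p_value, orc$p, tolerance = 1e-12)
    expect_equal(res$statistic, orc$statistic)
  }
})

test_that("normal approximation tracks a permutation reference at n=20 vs 20", {
  set.seed(5)
  x <- rbeta(20, 2, 40) + 0.05
  y <- rbeta(20, 2, 40)
  res <- rank_sum_test(x, y)
  p_perm <- perm_ranksum_p(x, y, B = 1e5)
  expect_lt(abs(res$p_value - p_perm), 0.01)
})

test_that("BH step-up matches hand-computed and brute-force values", {
  expect_equal(bh_adjust(0.03), 0.03)                    # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA p-values excluded from m and preserved in place
  q <- bh_adjust(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], brute_bh(c(0.01, 0.02)))
  set.seed(17)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in sorted order
  }
})

test_that("significance requires both the FDR and the 5% delta threshold", {
  set.seed(31)
  n_p <- 30
  # site 1: strong shift (0.20); site 2: real but tiny shift (0.03);
  # sites 3-6: null
  v <- matrix(rbeta(6 * 2 * n_p, 2, 40), 6)
  v[1, 1:n_p] <- v[1, 1:n_p] + 0.20
  v[2, 1:n_p] <- v[2, 1:n_p] + 0.03
  em <- toy_matrix(v)
  scr <- call_differential(em, fdr_q = 0.05, min_delta = 0.05)
  r <- scr$results[match(em$sites$site_id, scr$results$site_id), ]
  expect_true(r$significant[1])
  expect_identical(r$direction[1], "up")
  # q is small for site 2 but delta < 5%: not significant
  expect_lt(r$q_value[2], 0.05)
  expect_lt(abs(r$delta[2]), 0.05)
  expect_false(r$significant[2])
  expect_false(any(r$significant[3:6]))
})

test_that("up_only mode drops tumor-decreased sites", {
  set.seed(37)
  n_p <- 30
  v <- matrix(rbeta(2 * 2 * n_p, 2, 40), 2)
  v[1, 1:n_p] <- v[1, 1:n_p] + 0.2            # up in tumor
  v[2, n_p + 1:n_p] <- v[2, n_p + 1:n_p] + 0.2  # down in tumor
  em <- toy_matrix(v)
  both <- call_differential(em, direction = "both")$results
  up <- call_differential(em, direction = "up_only")$results
  expect_identical(sum(both$significant), 2L)
  expect_identical(up$significant, up$direction == "up")
  expect_identical(sum(up$significant), 1L)
})

test_that("screen calls are re-derivable from the raw matrix and order-invariant", {
  set.seed(41)
  sim <- simulate_cohort_matrix(cohort_sim_spec(
    n_pairs = 25, n_sites = 60, n_diff = 8, delta = 0.15,
    missing_rate = 0.1, seed = 99))
  scr <- call_differential(sim$matrix, min_pairs = 5)
  r <- scr$results
  # independent per-site recomputation of p, delta, then BH on the vector
  keep <- informative_filter(sim$matrix, 5)
  ti <- keep$condition == "tumor"
  p2 <- delta2 <- rep(NA_real_, nrow(keep$values))
  for (i in seq_len(nrow(keep$values))) {
    tv <- keep$values[i, ti]; nv <- keep$values[i, !ti]
    p2[i] <- rank_sum_test(tv, nv)$p_value
    delta2[i] <- mean(tv, na.rm = TRUE) - mean(nv, na.rm = TRUE)
  }
  q2 <- bh_adjust(p2)
  sig2 <- !is.na(q2) & q2 < 0.05 & abs(delta2) >= 0.05
  ix <- match(keep$sites$site_id, r$site_id)
  expect_equal(r$p_value[ix], p2)
  expect_equal(r$delta[ix], delta2, tolerance = 1e-12)
  expect_identical(r$significant[ix], sig2)

  # permuting site rows and sample columns permutes the output only
  perm_s <- sample(nrow(sim$matrix$values))
  perm_c <- sample(ncol(sim$matrix$values))
  em_p <- editing_matrix(sim$matrix$values[perm_s, perm_c],
                         sim$matrix$sites[perm_s, ],
                         sim$matrix$condition[perm_c],
                         sim$matrix$pair_id[perm_c])
  r_p <- call_differential(em_p, min_pairs = 5)$results
  expect_equal(r_p[names(r)], r[names(r)])
})

test_that("feature summary counts significant sites per class, multi-label", {
  r <- data.frame(chrom = "chr1", pos = 1:4,
                  site_id = paste0("chr1:", 1:4),
                  significant = c(TRUE, TRUE, TRUE, FALSE),
                  stringsAsFactors = FALSE)
  ann <- data.frame(site_id = paste0("chr1:", 1:3))
  ann$labels <- list(c("3UTR", "exon"), c("3UTR", "exon"), "intron")
  fs <- suppressWarnings(feature_summary(r, ann))
  expect_identical(fs$n_sites[fs$feature == "3UTR"], 2L)
  expect_identical(fs$n_sites[fs$feature == "exon"], 2L)
  expect_identical(fs$n_sites[fs$feature == "intron"], 1L)
  expect_identical(attr(fs, "n_significant"), 3L)
  expect_identical(attr(fs, "total"), 5L)  # multi-label inflates the total
  # unannotated significant site warns and is tallied
  r2 <- rbind(r, data.frame(chrom = "chr1", pos = 9, site_id = "chr1:9",
                            significant = TRUE))
  expect_warning(fs2 <- feature_summary(r2, ann), "unannotated")
  expect_identical(fs2$n_sites[fs2$feature == "unannotated"], 1L)
})
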