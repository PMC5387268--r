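test_that("interval fraction measures the largest consecutive run", {
  expect_equal(interval_fraction(c(4, 5, 6, 7)), 1)
  expect_equal(interval_fraction(c(1, 2, 3, 5)), 0.75)
  expect_equal(interval_fraction(c(1, 3, 5, 7)), 0.25)  # 1/N, no consecutive pair
  expect_equal(interval_fraction(10), 1)
  expect_error(interval_fraction(integer(0)), "empty")
})

test_that("extraction applies the interval criterion, de-duplicates across
           scales and filters inflated communities", {
  # 10 masked bins; interval community {3..6} at scales 2-4, a scattered
  # community {1,2,3,5} (P_int = 0.75) at scale 1, singletons elsewhere
  scattered <- c(1, 1, 1, 9, 1, 2, 3, 4, 5, 6)       # {1,2,3,5} + noise ids
  interval <- c(7, 8, 2, 2, 2, 2, 9, 10, 11, 12)      # {3..6}
  parts <- list(make_partition(scattered, 1),
                make_partition(interval, 2),
                make_partition(interval, 3),
                make_partition(interval, 4))
  ic <- extract_interval_communities(parts, bin_size = 1e5, chrom = "chrT")
  expect_equal(nrow(ic), 1)
  expect_equal(ic$masked_start, 2)
  expect_equal(ic$masked_end, 6)
  expect_equal(ic$scales[[1]], 2:4)
  expect_equal(ic$n_scales, 3)
  expect_equal(ic$start, 2e5)
  expect_equal(ic$length, 4e5)
  expect_equal(ic$inflation, 1)

  # invariants: every reported community has P_int >= threshold, size >= 2
  expect_true(all(ic$p_int >= 0.95))
  expect_true(all(ic$masked_end - ic$masked_start >= 2))

  # de-duplication is idempotent
  expect_identical(extract_interval_communities(parts, bin_size = 1e5,
                                                chrom = "chrT"), ic)

  # the same interval straddling a 30-bin masked gap inflates 2.5x and is
  # dropped at the default ceiling of 2
  map2 <- masked_index_map(c(1:10, 41:50), 50)
  lab <- c(rep(1, 10), rep(2, 10))
  parts2 <- list(make_partition(lab, 1))
  keep <- extract_interval_communities(parts2, map = map2, bin_size = 1e5)
  expect_equal(nrow(keep), 2)  # each arm alone is uninflated
  lab_all <- rep(1, 20)
  parts3 <- list(make_partition(lab_all, 1))
  dropped <- extract_interval_communities(parts3, map = map2, bin_size = 1e5)
  expect_equal(nrow(dropped), 0)
  kept_loose <- extract_interval_communities(parts3, map = map2,
                                             bin_size = 1e5, inflation_max = 3)
  expect_equal(kept_loose$inflation, 2.5)
})

test_that("borders: per-scale min rule, cross-scale max rule, k-1 counting", {
  # two adjacent communities of 10 and 30 bins -> one border, length 10
  sc1 <- data.frame(scale_index = 1, masked_start = c(0, 10),
                    masked_end = c(10, 40), size = c(10, 30),
                    p_int = 1)
  b <- community_borders(sc1)
  expect_equal(b$position, 10)
  expect_equal(b$associated_length, 10)
  # in genomic units (1 Mb and 3 Mb at 100 kb bins -> border length 1 Mb)
  expect_equal(community_borders(sc1, bin_size = 1e5)$associated_length, 1e6)

  # same border at three scales with per-scale lengths {5, 12, 8} -> 12
  sc3 <- do.call(rbind, lapply(1:3, function(s) {
    left <- c(5, 12, 8)[s]
    data.frame(scale_index = s, masked_start = c(20 - left, 20),
               masked_end = c(20, 20 + left + 1), size = 1, p_int = 1)
  }))
  expect_equal(community_borders(sc3)$associated_length, 12)

  # a partition tiling a component with k intervals has k-1 borders
  set.seed(8)
  for (rep in 1:10) {
    k <- sample(2:8, 1)
    cuts <- sort(sample(1:29, k - 1))
    starts <- c(0, cuts); ends <- c(cuts, 30)
    sck <- data.frame(scale_index = 1, masked_start = starts,
                      masked_end = ends, size = ends - starts, p_int = 1)
    expect_equal(nrow(community_borders(sck)), k - 1)
    # border positions are exactly the internal interval endpoints
    expect_equal(community_borders(sck)$position, cuts)
  }

  # non-touching intervals produce no border
  gap <- data.frame(scale_index = 1, masked_start = c(0, 12),
                    masked_end = c(10, 20), size = c(10, 8), p_int = 1)
  expect_equal(nrow(community_borders(gap)), 0)
})

test_that("border conservation proportions across scale pairs", {
  mk <- function(scale, cuts, total = 40) {
    starts <- c(0, cuts); ends <- c(cuts, total)
    data.frame(scale_index = scale, masked_start = starts, masked_end = ends,
               size = ends - starts, p_int = 1)
  }
  # s1 borders {10,20,30}; s2 borders {10,30}: all s2 borders conserved at
  # s1; with roles swapped the proportion is 2/3
  sc <- rbind(mk(1, c(10, 20, 30)), mk(2, c(10, 30)))
  P <- border_conservation(sc)
  expect_equal(P[1, 2], 1)
  sc_r <- rbind(mk(1, c(10, 30)), mk(2, c(10, 20, 30)))
  expect_equal(border_conservation(sc_r)[1, 2], 2 / 3)

  # perfectly nested three-level hierarchy: every proportion is 1
  sc_n <- rbind(mk(1, c(5, 10, 15, 20, 25, 30, 35)),
                mk(2, c(10, 20, 30)), mk(3, 20))
  Pn <- border_conservation(sc_n)
  expect_true(all(Pn[upper.tri(Pn)] == 1, na.rm = TRUE))
  expect_equal(sum(!is.na(Pn)), 3)

  # a scale without borders contributes missing entries, not zeros
  sc_e <- rbind(mk(1, c(10, 20)), mk(2, integer(0)))
  expect_true(all(is.na(border_conservation(sc_e))))

  # +/- 1 pixel tolerance flag
  sc_t <- rbind(mk(1, c(11, 30)), mk(2, c(10, 30)))
  expect_equal(border_conservation(sc_t)[1, 2], 0.5)
  expect_equal(border_conservation(sc_t, tol_pixels = 1)[1, 2], 1)
})

test_that("length distribution recovers a planted power-law exponent", {
  # all lengths identical: one occupied bin, exponent undefined
  ld1 <- length_distribution(rep(5e5, 30), bin_size = 1e5)
  expect_true(is.na(ld1$alpha))
  expect_equal(sum(ld1$histogram$count), 30)
  expect_equal(ld1$histogram$count[ld1$histogram$l == 5.5e5], 30)

  # 5000 draws from density ~ l^(-1.3) on [2, 100] Mb; 1 Mb histogram
  # bins keep expected counts >= 1 over the whole fit range, where the
  # zero-truncated log-log regression is unbiased
  for (sd in 1:3) {
    l <- sample_domain_lengths(5000, alpha = -1.3, l_min = 2e6, l_max = 1e8,
                               seed = sd)
    ld <- length_distribution(l, bin_size = 1e6, fit_min = 2e6)
    expect_lt(abs(ld$alpha - (-1.3)), 0.1)
    expect_equal(sum(ld$histogram$count), 5000)
  }

  # fewer than 20 lengths: histogram returned, no fit
  ld2 <- length_distribution(l[1:10], bin_size = 1e6, fit_min = 2e6)
  expect_true(is.na(ld2$alpha))
})
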