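test_that("composite r2 is 1 for identical vectors and label-invariant", {
  set.seed(1)
  a <- rbinom(50, 2, 0.4)
  expect_equal(pairwise_r2(a, a), 1)
  for (i in 1:20) {
    x <- rbinom(30, 2, runif(1, 0.2, 0.8))
    y <- rbinom(30, 2, runif(1, 0.2, 0.8))
    if (var(x) == 0 || var(y) == 0) next
    r <- pairwise_r2(x, y)
    expect_equal(pairwise_r2(y, x), r)            # symmetric
    expect_equal(pairwise_r2(2 - x, y), r)        # allele-flip invariant
    expect_equal(pairwise_r2(x, 2 - y), r)
    expect_true(r >= 0 && r <= 1)
  }
  expect_true(is.na(pairwise_r2(rep(1, 10), rbinom(10, 2, 0.5))))
})

test_that("haplotype r2 matches the worked frequency example", {
  # 4 x AB, 1 x Ab, 2 x aB, 3 x ab over 10 haplotypes:
  # f(AB) = 0.4, f(A) = 0.5, f(B) = 0.6, D = 0.1, r2 = 1/6
  ha <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  hb <- c(1, 1, 1, 1, 0, 1, 1, 0, 0, 0)
  expect_equal(r2_haplotype(ha, hb), 0.1 ^ 2 / (0.5 * 0.5 * 0.6 * 0.4))
  # oracle: brute-force Pearson correlation of the allele indicators
  expect_equal(r2_haplotype(ha, hb), cor(ha, hb) ^ 2, tolerance = 1e-12)
})

test_that("EM estimator recovers haplotype r2 from collapsed genotypes", {
  set.seed(9)
  for (i in 1:10) {
    n <- 500
    # draw correlated haplotypes, pair them into diploids
    hA <- rbinom(2 * n, 1, 0.5)
    hB <- ifelse(runif(2 * n) < 0.8, hA, rbinom(2 * n, 1, 0.5))
    truth <- r2_haplotype(hA, hB)
    a <- hA[seq(1, 2 * n, 2)] + hA[seq(2, 2 * n, 2)]
    b <- hB[seq(1, 2 * n, 2)] + hB[seq(2, 2 * n, 2)]
    expect_equal(r2_em(a, b), truth, tolerance = 0.05)
  }
})

test_that("independent loci at large n have near-zero r2", {
  set.seed(2)
  a <- rbinom(10000, 2, 0.3)
  b <- rbinom(10000, 2, 0.4)
  expect_lt(pairwise_r2(a, b), 0.01)
})

test_that("pair sampling is exhaustive, distinct and seed-deterministic", {
  g <- make_hwe_geno(30, 3, seed = 4)
  dm <- m1_positions(g)
  pr <- sample_pairs(g, "1", dm, n_pairs = 10, seed = 1)
  expect_equal(nrow(pr), 3)  # all 3 pairs of 3 SNPs
  g2 <- make_hwe_geno(40, 60, seed = 5)
  dm2 <- m1_positions(g2)
  p1 <- sample_pairs(g2, "1", dm2, n_pairs = 500, seed = 7)
  p2 <- sample_pairs(g2, "1", dm2, n_pairs = 500, seed = 7)
  p3 <- sample_pairs(g2, "1", dm2, n_pairs = 500, seed = 8)
  expect_identical(p1, p2)
  expect_false(identical(p1$snp_a, p3$snp_a))
  expect_equal(nrow(p1), 500)
  expect_false(any(duplicated(paste(p1$snp_a, p1$snp_b))))
})

test_that("r2 values do not depend on the map method, only distances do", {
  g <- make_hwe_geno(40, 50, seed = 6)
  mA <- m1_positions(g)
  mB <- m2_positions(g, c("1" = 2.5))
  pA <- sample_pairs(g, "1", mA, n_pairs = 200, seed = 3)
  pB <- sample_pairs(g, "1", mB, n_pairs = 200, seed = 3)
  expect_equal(pA$r2, pB$r2)
  expect_equal(pB$distance_cm, 2.5 * pA$distance_cm)
})

test_that("decay fit reproduces a constant and clamps predictions", {
  set.seed(10)
  d <- runif(400, 0.5, 50)
  grid <- seq(0.5, 50, length.out = 100)
  fit <- fit_decay(d, rep(0.3, 400), grid)
  expect_equal(fit, rep(0.3, 100), tolerance = 1e-6)
  # heavy noise never pushes predictions outside [0, 1]
  fitn <- fit_decay(d, pmax(pmin(rnorm(400, 0.02, 0.2), 1), 0), grid)
  expect_true(all(fitn >= 0 & fitn <= 1))
  # refuses with too few pairs in range
  expect_true(all(is.na(fit_decay(d[1:10], rep(0.3, 10), grid))))
})

test_that("decay fit tracks a known monotone curve within noise", {
  set.seed(11)
  n <- 4000
  d <- runif(n, 0.5, 60)
  truth <- function(x) 1 / (1 + 0.4 * x)
  r2 <- truth(d) + rnorm(n, 0, 0.05)
  grid <- seq(0.5, 50, length.out = 200)
  fit <- fit_decay(d, r2, grid)
  inner <- grid > 2 & grid < 45
  se <- 0.05 / sqrt(n * 0.05)  # noise SE within a smoothing window
  expect_lt(max(abs(fit[inner] - truth(grid[inner]))), 2 * se * 4)
})

test_that("replicate grids have zero variance for identical replicates", {
  g <- make_hwe_geno(30, 40, seed = 12)
  dm <- m1_positions(g)
  grid <- seq(0.5, 3.5, length.out = 20)
  # exhaustive sampling (n_pairs > total) makes replicates identical
  rg <- suppressWarnings(
    replicate_grid(g, "1", dm, grid, n_pairs = 10000, n_reps = 3,
                   seed = 1, min_pairs = 20))
  expect_equal(max(rg$var), 0)
  expect_equal(rg$n_reps, 3)
})

test_that("inverse-variance combination matches the hand example", {
  cc <- combine_chromosomes(c(0.3, 0.6), c(0.01, 0.04))
  expect_equal(cc$mean, 0.36)
  expect_equal(cc$se, sqrt(1 / 125))
  # equal variances reduce to the plain mean
  cc2 <- combine_chromosomes(c(0.2, 0.4, 0.6), c(0.02, 0.02, 0.02))
  expect_equal(cc2$mean, 0.4)
  # single chromosome: its mean, se = sqrt(var)
  cc3 <- combine_chromosomes(0.5, 0.04)
  expect_equal(cc3$mean, 0.5)
  expect_equal(cc3$se, 0.2)
  # zero variance: weight capped, mean stays defined
  cc4 <- combine_chromosomes(c(0.2, 0.4), c(0, 0.1))
  expect_equal(cc4$mean, 0.3)
  expect_true(cc4$lo <= cc4$mean && cc4$mean <= cc4$hi)
})

test_that("ld_decay on an equilibrium population is non-increasing", {
  cfg <- sim_config(ne = 50, n_chromosomes = 2, chr_length_cm = 100,
                    n_snps = 400, burnin = 200, sample_size = 50,
                    seed = 31)
  sim <- simulate_population(cfg)
  g <- suppressWarnings(filter_maf(apply_qc(sim$geno)$geno, 0.05))
  ld <- suppressWarnings(
    ld_decay(g, sim$truth$map, grid_points = 100, n_pairs = 2000,
             n_reps = 4, seed = 32))
  expect_s3_class(ld, "ld_decay")
  r2 <- ld$combined$r2
  # decreasing overall; band means decrease up to the sampling floor
  # (about 1/n) that dominates beyond ~20 cM at this sample size
  expect_lt(r2[length(r2)], r2[1] / 3)
  b1 <- mean(r2[ld$grid_cm < 5])
  b2 <- mean(r2[ld$grid_cm >= 5 & ld$grid_cm < 20])
  b3 <- mean(r2[ld$grid_cm >= 20])
  expect_gt(b1, b2)
  expect_gt(b2, b3 - 1 / nrow(g$dosage))
  expect_true(all(ld$combined$ci95_low <= ld$combined$r2 + 1e-12))
  # serialization round-trip sanity
  path <- tempfile()
  write_ld_grid(ld, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 100)
  expect_equal(df$weighted_r2, ld$combined$r2, tolerance = 1e-9)
})
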