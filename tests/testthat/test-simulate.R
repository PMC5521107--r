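test_that("simulated maps honor the regime construction", {
  # single regime at 1 cM/Mb: truth coincides with M1
  sm <- simulate_map(data.frame(length_mb = 100, rate_cm_per_mb = 1),
                     n_snps = 300, seed = 2)
  expect_equal(sm$truth$genetic_cm, sm$truth$position_bp / 1e6,
               tolerance = 1e-9)
  # two regimes: total cM is exactly sum(length x rate)
  sm2 <- simulate_map(data.frame(length_mb = c(40, 60),
                                 rate_cm_per_mb = c(0.5, 2.5)),
                      n_snps = 300, seed = 3)
  expect_equal(sm2$total_cm, 40 * 0.5 + 60 * 2.5)
  # anchors average the requested genetic spacing
  sp <- diff(sm2$anchors$genetic_cm)
  expect_equal(mean(sp), 0.5, tolerance = 0.01)
})

test_that("allele-frequency drift variance matches p(1-p)/2N per generation", {
  # one effectively unlinked chromosome (huge map), fixed initial
  # frequency, a few generations of drift
  n_rep <- 40
  N <- 50
  gens <- 6  # burn-in generations simulated after the founders
  p_var <- vapply(seq_len(n_rep), function(r) {
    cfg <- suppressWarnings(
      sim_config(ne = N, n_chromosomes = 1, chr_length_cm = 1e5,
                 n_snps = 60, init_maf = 0.5, burnin = gens,
                 sample_size = N, seed = 5000 + r))
    sim <- simulate_population(cfg)
    mean((sim$truth$allele_freq - 0.5) ^ 2)
  }, numeric(1))
  # founder sampling counts as one binomial round, then one per generation
  expected <- 0.25 * (1 - (1 - 1 / (2 * N)) ^ (gens + 1))
  expect_equal(mean(p_var), expected, tolerance = 0.2)
})

test_that("equilibrium r2 decreases with distance and matches Sved roughly", {
  cfg <- sim_config(ne = 50, n_chromosomes = 1, chr_length_cm = 100,
                    n_snps = 500, burnin = 250, sample_size = 50,
                    seed = 17)
  sim <- simulate_population(cfg)
  g <- suppressWarnings(filter_maf(apply_qc(sim$geno)$geno, 0.05))
  pr <- sample_pairs(g, "1", sim$truth$map, n_pairs = 20000, seed = 18)
  bins <- cut(pr$distance_cm, c(0, 5, 10, 20, 40, 100))
  means <- tapply(pr$r2, bins, mean)
  expect_lt(cor(seq_along(means), means, method = "spearman"), 0)
  # Sved + 1/(2n) order-of-magnitude agreement at 5-10 cM
  sved <- 1 / (1 + 4 * 50 * 0.075) + 1 / (2 * nrow(g$dosage))
  expect_equal(unname(means[2]), sved, tolerance = 0.5)
})

test_that("inter-chromosomal r2 sits at the sampling floor", {
  cfg <- sim_config(ne = 60, n_chromosomes = 2, chr_length_cm = 100,
                    n_snps = 150, burnin = 240, sample_size = 60,
                    seed = 19)
  sim <- simulate_population(cfg)
  g <- suppressWarnings(filter_maf(apply_qc(sim$geno)$geno, 0.05))
  i1 <- which(g$snps$chromosome == "1")[1:40]
  i2 <- which(g$snps$chromosome == "2")[1:40]
  r2 <- mapply(function(a, b) pairwise_r2(g$dosage[, a], g$dosage[, b]),
               rep(i1, each = 40), rep(i2, times = 40))
  n <- nrow(g$dosage)
  expect_lt(mean(r2, na.rm = TRUE), 3 / n)
  expect_gt(mean(r2, na.rm = TRUE), 1 / (3 * n))
})

test_that("zero-length maps drift toward fixation-level LD", {
  # complete linkage: the whole chromosome shares one genealogy, so
  # surviving polymorphic pairs are nearly perfectly associated
  meds <- c()
  for (s in 20:34) {
    cfg <- suppressWarnings(
      sim_config(ne = 20, n_chromosomes = 1, chr_length_cm = 0,
                 n_snps = 80, init_maf = 0.5, burnin = 120,
                 sample_size = 20, seed = s))
    sim <- simulate_population(cfg)
    g <- sim$geno
    keep <- which(!is.na(maf(g)) & maf(g) > 0)
    if (length(keep) < 2) next  # chromosome-wide fixation
    idx <- utils::combn(keep[seq_len(min(12, length(keep)))], 2)
    r2 <- mapply(function(a, b)
      pairwise_r2(g$dosage[, a], g$dosage[, b]), idx[1, ], idx[2, ])
    meds <- c(meds, stats::median(r2, na.rm = TRUE))
  }
  expect_gt(length(meds), 0)
  expect_gt(stats::median(meds), 0.9)
})

test_that("final-generation pedigree references valid parents", {
  cfg <- suppressWarnings(
    sim_config(ne = 40, n_chromosomes = 1, chr_length_cm = 50,
               n_snps = 50, burnin = 20, sample_size = 30, seed = 22))
  sim <- simulate_population(cfg)
  ped <- sim$truth$pedigree
  expect_equal(nrow(ped), 30)
  expect_true(all(ped$parent1 >= 1 & ped$parent1 <= 40))
  expect_true(all(ped$parent2 >= 1 & ped$parent2 <= 40))
})

test_that("corruption adds exactly what it promises", {
  g <- make_hwe_geno(30, 60, seed = 23)
  # identity when nothing is requested
  id <- corrupt_geno(g, missing_rate = 0, duplicate_count = 0, seed = 1)
  expect_equal(id$geno$dosage[, colnames(g$dosage)], g$dosage)
  # three duplicates are all flagged by IBS
  cr <- corrupt_geno(g, duplicate_count = 3, seed = 2)
  expect_equal(nrow(cr$geno$dosage), 33)
  res <- suppressWarnings(ibs_duplicates(cr$geno, qc_config()))
  expect_gte(nrow(res$pairs), 3)
  expect_true(all(cr$manifest$duplicates$duplicate %in%
                    c(res$pairs$id_a, res$pairs$id_b)))
  # missingness lands at about the requested rate
  cm <- corrupt_geno(g, missing_rate = 0.1, seed = 3)
  expect_lt(abs(mean(is.na(cm$geno$dosage)) - 0.1), 0.03)
})

test_that("simulated X genotypes drive sex inference correctly", {
  g <- make_hwe_geno(40, 30, seed = 24)
  cx <- corrupt_geno(g, x_snps = 200, x_error_rate = 0.005,
                     sexes = rep(c("male", "female"), 20), seed = 4)
  inferred <- infer_sex(cx$geno)
  expect_equal(unname(inferred), cx$manifest$sexes)
})

test_that("fixture datasets are byte-identical across runs at a seed", {
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  fixture_dataset("tiny", d1, seed = 5)
  fixture_dataset("tiny", d2, seed = 5)
  for (f in c("genotypes.ped", "genotypes.map", "breeds.tsv",
              "linkage_map.tsv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  g <- read_ped_map(file.path(d1, "genotypes.ped"),
                    file.path(d1, "genotypes.map"))
  expect_equal(dim(g$dosage), c(50L, 500L))
  unlink(c(d1, d2), recursive = TRUE)
})
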