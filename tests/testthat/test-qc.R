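test_that("call rate counts non-missing proportions on both axes", {
  g <- geno(matrix(c(0L, 1L, 2L, NA), 1, 4),
            data.frame(snp_id = paste0("s", 1:4), chromosome = "1",
                       position_bp = 1:4))
  expect_equal(unname(call_rate(g, "animal")), 0.75)
  expect_equal(unname(call_rate(g, "snp")), c(1, 1, 1, 0))
  g2 <- make_hwe_geno(5, 4)
  expect_true(all(call_rate(g2, "snp") == 1))
})

test_that("MAF matches hand-computed genotype counts", {
  # 25 AA + 50 Aa + 25 aa -> 0.5; 90 AA + 10 Aa -> 0.05; monomorphic -> 0
  d <- cbind(rep(c(0L, 1L, 2L), c(25, 50, 25)),
             rep(c(0L, 1L), c(90, 10)),
             rep(0L, 100))
  g <- geno(d, data.frame(snp_id = c("a", "b", "c"), chromosome = "1",
                          position_bp = 1:3))
  expect_equal(unname(maf(g)), c(0.5, 0.05, 0))
  # boundary: MAF 0.05 is retained under the strictly-lower-than rule
  expect_equal(ncol(filter_maf(g, 0.05)$dosage), 2L)
})

test_that("MAF spectrum uses left-open right-closed bins and sums to 100", {
  sp <- maf_spectrum(c(0.005, 0.05, 0.45))
  expect_equal(unname(sp[c(1, 2, 7)]), rep(100 / 3, 3))
  expect_equal(sum(sp), 100)
  expect_equal(unname(maf_spectrum(rep(0.5, 8))[7]), 100)
  set.seed(1)
  expect_equal(sum(maf_spectrum(runif(1000, 0, 0.5))), 100)
})

test_that("HWE chi-square matches an independent tail oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)
  # oracle: recompute the 1-df statistic by hand and take the tail
  oracle <- function(aa, ab, bb) {
    n <- aa + ab + bb; p <- (2 * aa + ab) / (2 * n)
    e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
    pchisq(sum((c(aa, ab, bb) - e)^2 / e), 1, lower.tail = FALSE)
  }
  expect_equal(hwe_test(0, 100, 0), oracle(0, 100, 0), tolerance = 1e-12)
  expect_lt(hwe_test(0, 100, 0), 1e-6)
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  set.seed(42)
  for (i in 1:50) {
    cnt <- rmultinom(1, 200, c(0.3, 0.5, 0.2))
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-10)
  }
  # exact option agrees with chi-square in direction for gross departures
  expect_lt(hwe_test(0, 100, 0, method = "exact"), 1e-6)
  expect_gt(hwe_test(25, 50, 25, method = "exact"), 0.5)
})

test_that("sex inference applies the strict 3% X-heterozygosity rule", {
  x0 <- matrix(rep(c(0L, 2L), 50), 1)          # 0% het
  x5 <- matrix(c(rep(1L, 5), rep(0L, 95)), 1)  # 5% het
  x3 <- matrix(c(rep(1L, 3), rep(0L, 97)), 1)  # exactly 3% -> male
  expect_equal(infer_sex(x0), "male")
  expect_equal(infer_sex(x5), "female")
  expect_equal(infer_sex(x3), "male")
  expect_equal(infer_sex(matrix(NA_integer_, 1, 10)), "unknown")
})

test_that("IBS flags duplicates, the 0.95 boundary, and spares unrelated", {
  g <- make_hwe_geno(6, 40, seed = 11)
  d <- g$dosage
  d <- rbind(d, d[1, ])  # exact duplicate
  # boundary pair: differs by one allele at 4 of 40 markers -> IBS 0.95
  bnd <- d[2, ]; bnd[1:4] <- bnd[1:4] + ifelse(bnd[1:4] <= 1, 1L, -1L)
  d <- rbind(d, bnd)
  an <- data.frame(animal_id = sprintf("B%02d", seq_len(nrow(d))))
  g2 <- geno(d, g$snps, an)
  res <- suppressWarnings(ibs_duplicates(g2, qc_config()))
  key <- paste(res$pairs$id_a, res$pairs$id_b)
  expect_true("B01 B07" %in% key)            # duplicate, IBS 1
  expect_equal(res$pairs$ibs[key == "B01 B07"], 1)
  expect_true("B02 B08" %in% key)            # boundary, IBS exactly 0.95
  expect_equal(res$pairs$ibs[key == "B02 B08"], 0.95)
  expect_equal(length(key), 2L)              # unrelated pairs not flagged
})

test_that("expected IBS for independent MAF-0.5 loci is about 0.625", {
  # brute-force enumeration over genotype pairs under HWE at p = 0.5
  pg <- c(0.25, 0.5, 0.25)
  e_ibs <- sum(outer(pg, pg) * (2 - abs(outer(0:2, 0:2, "-"))) / 2)
  expect_equal(e_ibs, 0.625)
  g <- make_hwe_geno(2, 4000, maf_range = c(0.5, 0.5), seed = 5)
  res <- suppressWarnings(ibs_duplicates(g, qc_config()))
  expect_equal(nrow(res$pairs), 0L)
  d <- g$dosage
  ibs <- mean((2 - abs(d[1, ] - d[2, ])) / 2)
  expect_equal(ibs, e_ibs, tolerance = 0.03)
})

test_that("QC cascade removes exactly the planted problems", {
  fx <- planted_qc_fixture(seed = 7)
  res <- suppressWarnings(apply_qc(fx$geno, qc_config()))
  rep <- res$report
  expect_equal(rep$snps_removed$snp_call_rate, fx$planted$allmiss)
  expect_equal(rep$snps_removed$maf, fx$planted$mono)
  expect_equal(rep$snps_removed$hwe, fx$planted$hwe_bad)
  expect_equal(sort(rep$snps_removed$non_autosomal),
               sort(grep("^x", fx$geno$snps$snp_id, value = TRUE)))
  expect_equal(rep$animals_removed$call_rate, fx$planted$lowcall)
  expect_equal(rep$animals_removed$ibs_duplicate, fx$planted$duplicate)
  expect_equal(rep$flags$sex_mismatch, fx$planted$missex)
  # counts reconcile
  expect_equal(rep$after[1],
               rep$before[1] - length(unlist(rep$animals_removed)))
  expect_equal(rep$after[2],
               rep$before[2] - length(unlist(rep$snps_removed)))
})

test_that("QC is idempotent: second pass removes nothing", {
  fx <- planted_qc_fixture(seed = 9)
  first <- suppressWarnings(apply_qc(fx$geno, qc_config()))
  second <- suppressWarnings(apply_qc(first$geno, qc_config()))
  expect_equal(second$geno$dosage, first$geno$dosage)
  expect_equal(length(unlist(second$report$snps_removed)), 0L)
  expect_equal(length(unlist(second$report$animals_removed)), 0L)
})

test_that("combined mode removes a SNP only when it fails HWE everywhere", {
  set.seed(21)
  n <- 40
  mk <- function(allhet) if (allhet) rep(1L, n) else
    rbinom(n, 1, 0.4) + rbinom(n, 1, 0.4)
  # SNP 'part': fails in groups 1-2 only; SNP 'full': fails in all 3
  groups <- rep(c("g1", "g2", "g3"), each = n)
  d <- cbind(
    part = c(mk(TRUE), mk(TRUE), mk(FALSE)),
    full = rep(1L, 3 * n),
    ok = c(mk(FALSE), mk(FALSE), mk(FALSE)))
  g <- geno(d, data.frame(snp_id = c("part", "full", "ok"),
                          chromosome = "1", position_bp = 1:3))
  res <- suppressWarnings(
    apply_qc(g, qc_config(mode = "combined"), groups = groups))
  expect_equal(res$report$snps_removed$hwe, "full")
  expect_true(all(c("part", "ok") %in% res$geno$snps$snp_id))
})

test_that("breed groups follow the composition rules exactly", {
  expect_equal(assign_breed_group(c(Rom = 0.8)), "Rom")
  expect_equal(assign_breed_group(c(Rom = 0.3, Coop = 0.3, Tex = 0.3)),
               "CompRCPT")
  expect_equal(assign_breed_group(c(Rom = 0.2, Coop = 0.2, Tex = 0.1)),
               "Comprcp2")
  expect_error(assign_breed_group(c(Rom = -0.1)), "non-negative")

  # exhaustive grid against a brute-force single-composition evaluator
  brute <- function(rom, coop, peren, tex) {
    if (rom >= 0.75) return("Rom")
    if (coop >= 0.75) return("Coop")
    if (peren >= 0.75) return("Peren")
    if (tex >= 0.75) return("Tex")
    rcp <- rom + coop + peren
    if (rcp > 0.5 && tex < 0.25) return("CompRCP")
    if (rcp > 0.5 && tex >= 0.25) return("CompRCPT")
    if (rcp > 0.3 && rcp <= 0.5) return("Comprcp2")
    "unassigned"
  }
  grid <- expand.grid(Rom = seq(0, 1, 0.25), Coop = seq(0, 1, 0.25),
                      Peren = seq(0, 1, 0.25), Tex = seq(0, 1, 0.25))
  grid <- grid[rowSums(grid) <= 1, ]
  got <- assign_breed_group(grid)
  want <- mapply(brute, grid$Rom, grid$Coop, grid$Peren, grid$Tex)
  expect_equal(got, unname(want))
})
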