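snp_df <- function(bp, chr = "1") {
  data.frame(snp_id = sprintf("s%04d", seq_along(bp)), chromosome = chr,
             position_bp = bp)
}

test_that("M1 scales physical position by the genome-wide ratio", {
  m <- m1_positions(snp_df(c(0, 1e8)))
  expect_equal(m$genetic_cm, c(0, 100))
  m2 <- m1_positions(snp_df(c(0, 1e8)), genome_ratio = 1.51)
  expect_equal(m2$genetic_cm, c(0, 151))
})

test_that("chromosome ratios reproduce printed per-chromosome values", {
  lk <- linkage_map(data.frame(
    snp_id = c("a1", "a2", "b1", "b2"),
    chromosome = c("OAR1", "OAR1", "OAR14", "OAR14"),
    position_bp = c(0, 275e6, 0, 62e6),
    genetic_cm = c(0, 323, 0, 118)))
  r <- chromosome_ratios(lk)
  expect_equal(round(r[["OAR1"]], 2), 1.17)
  expect_equal(round(r[["OAR14"]], 2), 1.90)
  expect_error(chromosome_ratios(lk, physical_mb = c(OAR9 = 90)),
               "OAR9")
})

test_that("M2 applies per-chromosome ratios and reduces to M1 at 1.0", {
  snps <- snp_df(c(0, 5e7, 1e8))
  m2 <- m2_positions(snps, c("1" = 1.3))
  expect_equal(m2$genetic_cm, c(0, 65, 130))
  expect_equal(m2_positions(snps, c("1" = 1))$genetic_cm,
               m1_positions(snps)$genetic_cm)
  expect_error(m2_positions(snps, c("2" = 1.3)), "no ratio")
})

test_that("interval trimming removes negative and extreme-ratio intervals", {
  # uniform 1 cM/Mb map: only ties at the max reach the 99.9 percentile
  lk <- linkage_map(data.frame(snp_id = sprintf("a%02d", 1:21),
                               chromosome = "1",
                               position_bp = (0:20) * 1e6,
                               genetic_cm = 0:20))
  iv <- interval_ratios(lk)
  expect_equal(nrow(iv), 20)
  expect_false(any(iv$removed))  # ties at the max are not "extreme"
  # one negative interval in an otherwise increasing map
  cm <- c(0, 1, 2, 1.5, 3, 4, 5, 6, 7, 8, 9)
  lk2 <- linkage_map(data.frame(snp_id = sprintf("b%02d", 1:11),
                                chromosome = "1",
                                position_bp = (0:10) * 1e6,
                                genetic_cm = cm))
  iv2 <- interval_ratios(lk2)
  expect_equal(iv2$reason[3], "negative_cm")
  expect_true(iv2$removed[3])
  # a single 2-SNP chromosome yields one interval with the plain ratio
  lk3 <- linkage_map(data.frame(snp_id = c("c1", "c2"), chromosome = "2",
                                position_bp = c(0, 2e6),
                                genetic_cm = c(0, 5)))
  iv3 <- interval_ratios(rbind(lk2, lk3))
  expect_equal(iv3$ratio[iv3$chromosome == "2"], 2.5)
})

test_that("M3 reproduces a linear map and stays monotone on bad anchors", {
  anchors <- linkage_map(data.frame(
    snp_id = sprintf("a%02d", 1:41), chromosome = "1",
    position_bp = seq(0, 1e8, length.out = 41),
    genetic_cm = seq(0, 130, length.out = 41)))
  chip <- snp_df(seq(1e6, 9.9e7, length.out = 200))
  m3 <- m3_positions(anchors, chip)
  expect_equal(m3$genetic_cm, chip$position_bp / 1e6 * 1.3,
               tolerance = 1e-6)
  # one inverted anchor pair: output still non-decreasing
  bad <- anchors
  bad$genetic_cm[20] <- bad$genetic_cm[21] + 2
  m3b <- m3_positions(linkage_map(bad), chip)
  expect_true(all(diff(m3b$genetic_cm) >= 0))
  # too few anchors falls back to M2
  expect_warning(m3_positions(anchors[1:5, ], chip), "falling back")
})

test_that("recombination profile is flat for M1/M2 and integrates back", {
  chip <- snp_df(seq(0, 1e8, length.out = 50))
  prof1 <- recombination_profile(m1_positions(chip))
  expect_true(all(abs(prof1$ratio - 1) < 1e-9))
  m2 <- m2_positions(chip, c("1" = 1.7))
  prof2 <- recombination_profile(m2)
  expect_true(all(abs(prof2$ratio - 1.7) < 1e-9))
  # telescoping: sum(ratio * delta_mb) equals the total genetic length
  tot <- sum(prof2$ratio * (prof2$end_bp - prof2$start_bp) / 1e6)
  expect_equal(tot, max(m2$genetic_cm) - min(m2$genetic_cm))
})

test_that("map summary reports the length-ratio correlation", {
  tab <- summary_stats_from_table(imf_chromosome_summary)
  expect_equal(round(attr(tab, "correlation"), 2), -0.70)
  expect_equal(round(attr(tab, "mean_ratio"), 2), 1.51)
  tot <- tab[tab$chromosome == "TOTAL", ]
  expect_equal(tot$physical_mb, 2439)
  expect_equal(tot$genetic_cm, 3421)
  expect_equal(tot$n_snps, 6448)
  # degenerate case: equal ratios -> correlation undefined
  lk <- linkage_map(data.frame(
    snp_id = sprintf("s%d", 1:6), chromosome = rep(c("1", "2", "3"), 2),
    position_bp = rep(c(0, 1e7), each = 3),
    genetic_cm = rep(c(0, 10), each = 3)))
  ms <- map_summary(lk)
  expect_true(is.na(attr(ms, "correlation")))
})

test_that("Kosambi conversion matches the closed form and round-trips", {
  expect_equal(kosambi_r(0), 0)
  expect_equal(kosambi_r(25), 0.5 * tanh(0.5))
  expect_equal(round(kosambi_r(25), 4), 0.2311)
  d <- c(0, 1, 5, 25, 80)
  expect_equal(kosambi_cm(kosambi_r(d)), d, tolerance = 1e-12)
})

test_that("UCSC track files have the 4-column format and round-trip", {
  m <- m1_positions(snp_df(c(1e6, 2e6)))
  path <- tempfile()
  write_ucsc_track(m, path)
  lines <- readLines(path)
  expect_true(startsWith(lines[1], "track"))
  expect_length(lines, 2)  # header + one interval
  df <- read_ucsc_track(path)
  expect_equal(df$prev_bp, 1e6)
  expect_equal(df$pos_bp, 2e6)
  expect_equal(df$value, 2)
  # rate track round-trips too
  prof <- recombination_profile(m)
  write_ucsc_track(prof, path, name = "recomb_rate")
  expect_equal(read_ucsc_track(path)$value, prof$ratio)
})

test_that("simulated two-regime maps are recovered best by M3", {
  rmse <- function(map, truth) sqrt(mean((map$genetic_cm -
                                            truth$genetic_cm)^2))
  worse <- 0
  for (s in 1:5) {
    sm <- simulate_map(data.frame(length_mb = c(50, 50),
                                  rate_cm_per_mb = c(0.5, 2.5)),
                       n_snps = 1000, anchors_per_cm = 2, seed = s)
    m1 <- m1_positions(sm$truth)
    r <- chromosome_ratios(sm$anchors,
                           physical_mb = stats::setNames(
                             max(sm$truth$position_bp) / 1e6, "1"))
    m2 <- m2_positions(sm$truth, r)
    m3 <- m3_positions(sm$anchors, sm$truth)
    e1 <- rmse(m1, sm$truth); e2 <- rmse(m2, sm$truth)
    e3 <- rmse(m3, sm$truth)
    expect_lt(e3, 2)
    if (e3 >= min(e1, e2)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})
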