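# in-code fixtures shared across test files

# clean genotypes in Hardy-Weinberg proportions, full call rate
make_hwe_geno <- function(n = 60, m = 30, maf_range = c(0.3, 0.5),
                          seed = 1, chromosome = "1", prefix = "s") {
  set.seed(seed)
  p <- runif(m, maf_range[1], maf_range[2])
  dosage <- sapply(p, function(pp) rbinom(n, 1, pp) + rbinom(n, 1, pp))
  snps <- data.frame(snp_id = sprintf("%s%03d", prefix, seq_len(m)),
                     chromosome = chromosome,
                     position_bp = seq_len(m) * 1e5)
  animals <- data.frame(animal_id = sprintf("A%03d", seq_len(n)),
                        sex = "unknown")
  geno(dosage, snps, animals)
}

# a QC torture fixture with six planted problems:
#   monomorphic SNP, all-missing SNP, HWE-violating SNP,
#   low-call-rate animal, exact duplicate pair, mis-sexed animal
planted_qc_fixture <- function(seed = 7) {
  set.seed(seed)
  n <- 60; m <- 120
  g <- make_hwe_geno(n, m, seed = seed)
  dosage <- g$dosage
  snps <- g$snps
  # planted SNPs
  extra <- cbind(mono = rep(0L, n),
                 allmiss = rep(NA_integer_, n),
                 hwe_bad = rep(1L, n))
  snps <- rbind(snps, data.frame(
    snp_id = c("mono", "allmiss", "hwe_bad"), chromosome = "1",
    position_bp = (m + 1:3) * 1e5))
  dosage <- cbind(dosage, extra)
  # X SNPs consistent with assigned sexes; animal A005 recorded male but
  # carries female-like X heterozygosity
  nx <- 40
  px <- runif(nx, 0.3, 0.5)
  sexes <- rep(c("male", "female"), length.out = n)
  missex <- "A005"
  xd <- t(sapply(seq_len(n), function(i) {
    truly_female <- sexes[i] == "female" ||
      g$animals$animal_id[i] == missex
    if (truly_female) rbinom(nx, 1, px) + rbinom(nx, 1, px)
    else 2L * rbinom(nx, 1, px)
  }))
  sexes[g$animals$animal_id == missex] <- "male"  # recorded, not true
  snps <- rbind(snps, data.frame(
    snp_id = sprintf("x%03d", seq_len(nx)), chromosome = "X",
    position_bp = seq_len(nx) * 1e5))
  dosage <- cbind(dosage, xd)
  animals <- data.frame(animal_id = g$animals$animal_id, sex = sexes)
  # low-call-rate animal: A010 loses 7 of the 120 clean autosomal SNPs
  # (call rate 113/120 = 0.94, below the 0.95 threshold after the X and
  # planted SNPs are gone)
  lowcall <- "A010"
  dosage[animals$animal_id == lowcall, 1:7] <- NA_integer_
  # duplicate pair: exact copy of A001
  dupof <- "A001"
  dosage <- rbind(dosage, dosage[animals$animal_id == dupof, ])
  animals <- rbind(animals,
                   data.frame(animal_id = "A001_dup",
                              sex = animals$sex[animals$animal_id == dupof]))
  list(geno = geno(dosage, snps, animals),
       planted = list(mono = "mono", allmiss = "allmiss",
                      hwe_bad = "hwe_bad", lowcall = lowcall,
                      duplicate = "A001_dup", missex = missex))
}

# build an ld_decay-shaped object from explicit per-chromosome curves,
# for testing downstream transforms without a full fit
fake_ld_fit <- function(means, vars, replicates, grid_cm,
                        method = "M1") {
  comb <- combine_chromosomes(means, vars)
  structure(list(grid_cm = grid_cm, method = method,
                 chromosomes = rownames(means), mean = means, var = vars,
                 replicates = replicates,
                 combined = data.frame(grid_cm = grid_cm, r2 = comb$mean,
                                       se = comb$se, ci95_low = comb$lo,
                                       ci95_high = comb$hi),
                 n_pairs = NA, n_reps = NA, seed = NA),
            class = "ld_decay")
}
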