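#' Quality-control configuration
#'
#' Defaults follow the standard SNP-chip workflow: animals with call rate
#' <= 0.95 removed, SNPs with call rate below 0.95 removed, monomorphic
#' SNPs removed, extreme Hardy-Weinberg departures at p <= 1e-6 removed,
#' duplicate detection on 2000 sampled autosomal markers at IBS >= 0.95,
#' sex called female when more than 3% of X-chromosome calls are
#' heterozygous. `maf_min_ld` (0.05) applies only to the LD stage input
#' (see [filter_maf()]), never to the diversity stage.
#'
#' @param snp_call_rate_min,animal_call_rate_min call-rate thresholds.
#' @param hwe_p_min SNPs with HWE p-value <= this are removed.
#' @param maf_min_diversity MAF floor at the diversity stage (strictly
#'   greater-than; 0 keeps all polymorphic SNPs).
#' @param maf_min_ld MAF floor for the LD stage (strictly lower-than rule:
#'   SNPs with MAF < 0.05 are removed).
#' @param ibs_threshold,ibs_marker_count duplicate-pair detection settings.
#' @param x_het_threshold heterozygosity fraction above which an animal's
#'   X chromosome is called female.
#' @param mode `"per_breed"` runs the HWE test within the supplied group;
#'   `"combined"` removes a SNP only when it fails HWE within every group.
#' @param hwe_method `"chisq"` (1-df goodness of fit, no continuity
#'   correction) or `"exact"`.
#' @param remove_sex_mismatch if `TRUE`, animals whose inferred sex
#'   contradicts the recorded sex are removed; otherwise only flagged.
#' @param seed seed for the IBS marker draw.
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(snp_call_rate_min = 0.95,
                      animal_call_rate_min = 0.95,
                      hwe_p_min = 1e-6,
                      maf_min_diversity = 0,
                      maf_min_ld = 0.05,
                      ibs_threshold = 0.95,
                      ibs_marker_count = 2000,
                      x_het_threshold = 0.03,
                      mode = c("per_breed", "combined"),
                      hwe_method = c("chisq", "exact"),
                      remove_sex_mismatch = FALSE,
                      seed = 1L) {
  mode <- match.arg(mode)
  hwe_method <- match.arg(hwe_method)
  props <- c(snp_call_rate_min, animal_call_rate_min, maf_min_diversity,
             maf_min_ld, ibs_threshold, x_het_threshold)
  stopifnot(all(props >= 0 & props <= 1), hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(snp_call_rate_min = snp_call_rate_min,
                 animal_call_rate_min = animal_call_rate_min,
                 hwe_p_min = hwe_p_min,
                 maf_min_diversity = maf_min_diversity,
                 maf_min_ld = maf_min_ld,
                 ibs_threshold = ibs_threshold,
                 ibs_marker_count = as.integer(ibs_marker_count),
                 x_het_threshold = x_het_threshold,
                 mode = mode, hwe_method = hwe_method,
                 remove_sex_mismatch = remove_sex_mismatch,
                 seed = as.integer(seed)),
            class = "qc_config")
}

#' Call rate per SNP or per animal
#'
#' @param g a [geno()] object.
#' @param axis `"snp"` or `"animal"`.
#' @return Named vector of non-missing proportions in `[0, 1]`.
#' @export
call_rate <- function(g, axis = c("snp", "animal")) {
  stopifnot(inherits(g, "geno"), length(g$dosage) > 0)
  axis <- match.arg(axis)
  ok <- !is.na(g$dosage)
  if (axis == "snp") colMeans(ok) else rowMeans(ok)
}

#' Minor allele frequency per SNP
#'
#' MAF = min(p, 1 - p) with p the frequency of the counted allele among
#' non-missing calls. SNPs with no non-missing calls get `NA`.
#'
#' @param g a [geno()] object.
#' @return Named numeric vector in `[0, 0.5]` (`NA` where undefined).
#' @export
maf <- function(g) {
  stopifnot(inherits(g, "geno"))
  n <- colSums(!is.na(g$dosage))
  p <- colSums(g$dosage, na.rm = TRUE) / (2 * n)
  p[n == 0] <- NA
  pmin(p, 1 - p)
}

#' MAF spectrum over bins
#'
#' Bins are left-open/right-closed, `(e_i, e_{i+1}]`, except the first
#' which is closed at 0, matching the usual "0.01 < MAF <= 0.05" style of
#' reporting. Returns percentages of SNPs per bin.
#'
#' @param x a [geno()] object or a numeric vector of MAFs.
#' @param bin_edges ascending proportions covering `[0, 0.5]`.
#' @return Named numeric vector of percentages summing to 100.
#' @export
maf_spectrum <- function(x, bin_edges = c(0, 0.01, 0.05, 0.1, 0.2,
                                          0.3, 0.4, 0.5)) {
  m <- if (inherits(x, "geno")) maf(x) else x
  m <- m[!is.na(m)]
  stopifnot(!is.unsorted(bin_edges), bin_edges[1] <= 0,
            bin_edges[length(bin_edges)] >= 0.5)
  k <- length(bin_edges) - 1L
  idx <- findInterval(m, bin_edges, left.open = TRUE, rightmost.closed = TRUE)
  idx[m <= bin_edges[1]] <- 1L  # first bin closed at its lower edge
  idx <- pmin(idx, k)
  counts <- tabulate(idx, nbins = k)
  lab <- paste0(ifelse(seq_len(k) == 1, "MAF <= ",
                       paste0(bin_edges[seq_len(k)], " < MAF <= ")),
                bin_edges[-1])
  stats::setNames(100 * counts / length(m), lab)
}

#' Hardy-Weinberg equilibrium test
#'
#' Tests observed genotype counts (hom-ref, het, hom-alt) against the
#' p^2 : 2pq : q^2 expectation at the sample allele frequency. The default
#' is the 1-df chi-square goodness-of-fit statistic without continuity
#' correction; `method = "exact"` uses the conditional exact test on the
#' heterozygote count (two-sided, summing genotype configurations with
#' probability no greater than the observed one).
#'
#' @param n_aa,n_ab,n_bb genotype counts (vectorized).
#' @param method `"chisq"` or `"exact"`.
#' @return p-values; `NA` where the total count is zero.
#' @export
hwe_test <- function(n_aa, n_ab, n_bb, method = c("chisq", "exact")) {
  method <- match.arg(method)
  n_aa <- as.numeric(n_aa); n_ab <- as.numeric(n_ab); n_bb <- as.numeric(n_bb)
  n <- n_aa + n_ab + n_bb
  if (method == "chisq") {
    p <- (2 * n_aa + n_ab) / (2 * n)
    q <- 1 - p
    e_aa <- n * p^2; e_ab <- 2 * n * p * q; e_bb <- n * q^2
    chi <- (n_aa - e_aa)^2 / e_aa + (n_ab - e_ab)^2 / e_ab +
      (n_bb - e_bb)^2 / e_bb
    # monomorphic: expectation matches observation exactly
    chi[p == 0 | p == 1] <- 0
    out <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
    out[n == 0] <- NA
    return(out)
  }
  mapply(function(a, h, b) {
    if (a + h + b == 0) return(NA_real_)
    hwe_exact_one(a, h, b)
  }, n_aa, n_ab, n_bb)
}

# conditional exact HWE p-value for one SNP: distribution of the
# heterozygote count h given n genotypes and n_a copies of allele A is
# P(h) = n! / (n_aa! h! n_bb!) * 2^h / choose(2n, n_a)
hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  if (n_a > n) {  # work with the minor allele
    n_a <- 2 * n - n_a
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
  }
  hets <- seq(n_a %% 2, n_a, by = 2)
  aa <- (n_a - hets) / 2
  bb <- n - aa - hets
  logp <- lfactorial(n) - lfactorial(aa) - lfactorial(hets) -
    lfactorial(bb) + hets * log(2) - lchoose(2 * n, n_a)
  logp <- logp - max(logp)
  pr <- exp(logp) / sum(exp(logp))
  obs <- pr[match(n_ab, hets)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' HWE p-values for every SNP of a genotype object
#'
#' @param g a [geno()] object.
#' @param method passed to [hwe_test()].
#' @return Named vector of p-values.
#' @export
hwe_scan <- function(g, method = c("chisq", "exact")) {
  d <- g$dosage
  n0 <- colSums(d == 0, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n2 <- colSums(d == 2, na.rm = TRUE)
  stats::setNames(hwe_test(n0, n1, n2, method = match.arg(method)),
                  g$snps$snp_id)
}

#' Infer sex from X-chromosome heterozygosity
#'
#' An animal is called female when strictly more than `threshold` (default
#' 3%) of its non-missing X-chromosome calls are heterozygous, male
#' otherwise; `"unknown"` when it has no non-missing X calls.
#'
#' @param g a [geno()] object (uses SNPs on chromosome `x_label`), or a
#'   dosage matrix of X genotypes.
#' @param threshold heterozygosity fraction.
#' @param x_label chromosome label of the X.
#' @return Character vector (`"male"`, `"female"`, `"unknown"`) per animal.
#' @export
infer_sex <- function(g, threshold = 0.03, x_label = "X") {
  x <- if (inherits(g, "geno")) {
    g$dosage[, g$snps$chromosome == x_label, drop = FALSE]
  } else as.matrix(g)
  if (ncol(x) == 0)
    return(rep("unknown", nrow(x)))
  nhet <- rowSums(x == 1, na.rm = TRUE)
  nobs <- rowSums(!is.na(x))
  out <- ifelse(nhet / nobs > threshold, "female", "male")
  out[nobs == 0] <- "unknown"
  out
}

#' Detect duplicate samples by identity-by-state
#'
#' IBS between two animals is the mean over markers of
#' `(2 - |d_i - d_j|) / 2`, using pairwise non-missing calls on a random
#' subset of autosomal markers. Pairs at or above the threshold are
#' flagged; from each flagged pair the member with the lower overall call
#' rate is marked for removal (ties broken towards the later animal id).
#'
#' @param g a [geno()] object.
#' @param config a [qc_config()].
#' @param seed seed for the marker draw (defaults to `config$seed`).
#' @return List with `pairs` (data frame: id_a, id_b, ibs) and `remove`
#'   (character vector of animal ids).
#' @export
ibs_duplicates <- function(g, config = qc_config(), seed = config$seed) {
  stopifnot(inherits(g, "geno"), nrow(g$dosage) >= 2)
  auto <- autosomal_snps(g)
  k <- config$ibs_marker_count
  if (length(auto) < k) {
    warning("only ", length(auto), " autosomal markers available; using all")
    sel <- auto
  } else {
    sel <- local_seed(seed, sample(auto, k))
  }
  d <- g$dosage[, sel, drop = FALSE]
  n <- nrow(d)
  ids <- g$animals$animal_id
  cr <- rowMeans(!is.na(g$dosage))
  pairs <- NULL
  for (i in seq_len(n - 1)) {
    di <- d[i, ]
    for (j in seq(i + 1, n)) {
      diff <- abs(di - d[j, ])
      ok <- !is.na(diff)
      if (!any(ok)) next
      ibs <- mean((2 - diff[ok]) / 2)
      if (ibs >= config$ibs_threshold)
        pairs <- rbind(pairs, data.frame(id_a = ids[i], id_b = ids[j],
                                         ibs = ibs,
                                         stringsAsFactors = FALSE))
    }
  }
  if (is.null(pairs))
    return(list(pairs = data.frame(id_a = character(), id_b = character(),
                                   ibs = numeric()),
                remove = character()))
  remove <- character()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$id_a[r]; b <- pairs$id_b[r]
    cra <- cr[match(a, ids)]; crb <- cr[match(b, ids)]
    remove <- c(remove, if (cra < crb) a else b)
  }
  list(pairs = pairs, remove = unique(remove))
}

#' Apply the full quality-control cascade
#'
#' Stages, in order: sex check (flag or remove recorded-vs-inferred
#' mismatches), SNP call rate, minor allele frequency (monomorphic SNPs
#' out under the strict `MAF > maf_min_diversity` rule), Hardy-Weinberg
#' (per group, or in combined mode removal only of SNPs failing within
#' every group), removal of non-autosomal SNPs, animal call rate
#' (`<= threshold` removed), and IBS duplicate removal.
#'
#' @param g a [geno()] object.
#' @param config a [qc_config()].
#' @param groups optional factor/character of breed-group labels per
#'   animal (required for `mode = "combined"`).
#' @return List with `geno` (the filtered object) and `report`
#'   (class `"qc_report"`).
#' @export
apply_qc <- function(g, config = qc_config(), groups = NULL) {
  stopifnot(inherits(g, "geno"))
  snps_removed <- list()
  animals_removed <- list()
  flags <- list()
  before <- dim(g$dosage)

  # sex check uses X SNPs before any are dropped
  has_x <- any(g$snps$chromosome == "X")
  if (has_x && any(g$animals$sex %in% c("male", "female"))) {
    inferred <- infer_sex(g, threshold = config$x_het_threshold)
    rec <- g$animals$sex
    mism <- which(rec %in% c("male", "female") & inferred != "unknown" &
                    inferred != rec)
    flags$sex_mismatch <- g$animals$animal_id[mism]
    if (config$remove_sex_mismatch && length(mism)) {
      animals_removed$sex_mismatch <- g$animals$animal_id[mism]
      g <- subset_geno(g, animals = -mism)
      if (!is.null(groups)) groups <- groups[-mism]
    }
  }

  # SNP call rate
  cr <- call_rate(g, "snp")
  drop <- which(cr < config$snp_call_rate_min)
  snps_removed$snp_call_rate <- g$snps$snp_id[drop]
  if (length(drop)) g <- subset_geno(g, snps = -drop)

  # MAF > floor (strict)
  m <- maf(g)
  drop <- which(is.na(m) | m <= config$maf_min_diversity)
  snps_removed$maf <- g$snps$snp_id[drop]
  if (length(drop)) g <- subset_geno(g, snps = -drop)

  # HWE on autosomal SNPs only (X genotypes in a mixed-sex sample fail
  # HWE by construction and are removed as non-autosomal below anyway)
  auto <- autosomal_snps(g)
  if (config$mode == "per_breed" || is.null(groups)) {
    p <- hwe_scan(g, method = config$hwe_method)
    drop <- which(!is.na(p) & p <= config$hwe_p_min)
  } else {
    fails <- NULL
    for (grp in unique(groups[!is.na(groups)])) {
      gg <- subset_geno(g, animals = which(groups == grp))
      p <- hwe_scan(gg, method = config$hwe_method)
      f <- !is.na(p) & p <= config$hwe_p_min
      fails <- if (is.null(fails)) f else fails & f
    }
    drop <- which(fails)
  }
  drop <- intersect(drop, auto)
  snps_removed$hwe <- g$snps$snp_id[drop]
  if (length(drop)) g <- subset_geno(g, snps = -drop)

  # non-autosomal SNPs out for all downstream stages
  nonauto <- setdiff(seq_len(ncol(g$dosage)), autosomal_snps(g))
  snps_removed$non_autosomal <- g$snps$snp_id[nonauto]
  if (length(nonauto)) g <- subset_geno(g, snps = -nonauto)

  # animal call rate (<= threshold removed, as the rule is quoted)
  acr <- call_rate(g, "animal")
  drop <- which(acr <= config$animal_call_rate_min)
  animals_removed$call_rate <- g$animals$animal_id[drop]
  if (length(drop)) {
    g <- subset_geno(g, animals = -drop)
    if (!is.null(groups)) groups <- groups[-drop]
  }

  # IBS duplicates
  if (nrow(g$dosage) >= 2) {
    dup <- ibs_duplicates(g, config)
    animals_removed$ibs_duplicate <- dup$remove
    flags$ibs_pairs <- dup$pairs
    if (length(dup$remove)) {
      idx <- match(dup$remove, g$animals$animal_id)
      g <- subset_geno(g, animals = -idx)
    }
  }

  if (length(g$dosage) == 0)
    stop("QC removed every animal or every SNP; nothing left to analyse")

  report <- structure(list(snps_removed = snps_removed,
                           animals_removed = animals_removed,
                           flags = flags,
                           before = before, after = dim(g$dosage)),
                      class = "qc_report")
  list(geno = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  animals: %d -> %d   SNPs: %d -> %d\n",
              x$before[1], x$after[1], x$before[2], x$after[2]))
  for (r in names(x$snps_removed))
    cat(sprintf("  SNPs removed (%s): %d\n", r, length(x$snps_removed[[r]])))
  for (r in names(x$animals_removed))
    cat(sprintf("  animals removed (%s): %d\n", r,
                length(x$animals_removed[[r]])))
  if (length(x$flags$sex_mismatch))
    cat("  sex mismatches flagged:",
        paste(x$flags$sex_mismatch, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a QC report
#'
#' `write_qc_report` emits JSON; `qc_counts_table` returns (and optionally
#' writes) a Before/After counts table.
#'
#' @param report a `"qc_report"`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

#' @rdname write_qc_report
#' @export
qc_counts_table <- function(report, path = NULL) {
  tab <- data.frame(item = c("animals", "snps"),
                    before = report$before, after = report$after)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

#' Apply the LD-stage MAF filter
#'
#' SNPs with MAF strictly lower than `min_maf` (default 0.05) are removed;
#' a SNP at exactly 0.05 is retained.
#'
#' @param g a [geno()] object.
#' @param min_maf threshold.
#' @return A filtered [geno()] object.
#' @export
filter_maf <- function(g, min_maf = 0.05) {
  m <- maf(g)
  keep <- which(!is.na(m) & m >= min_maf)
  subset_geno(g, snps = keep)
}

# evaluate expr under a temporary RNG state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
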