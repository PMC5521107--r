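#' Simulate a variable-rate genetic map with sparse anchors
#'
#' Builds a piecewise-linear true cM(bp) curve from recombination-rate
#' regimes, places chip SNPs uniformly along the physical axis, and
#' places linkage-map anchors at a fixed density on the genetic axis
#' (two per cM by default, the resolution of a typical mapping-flock
#' subset), reporting their exact true positions plus optional noise.
#'
#' @param regimes data frame with columns `length_mb` and
#'   `rate_cm_per_mb` (> 0), one row per constant-rate segment.
#' @param n_snps number of chip SNPs.
#' @param anchors_per_cm anchor density on the genetic axis.
#' @param seed integer seed.
#' @param chromosome chromosome label for the output tables.
#' @param anchor_noise_cm standard deviation of Gaussian noise added to
#'   anchor genetic positions (0 = exact).
#' @return List: `truth` (dense `"genetic_map"` of the chip SNPs with
#'   true cM), `anchors` (a [linkage_map()]), `total_cm`, `total_mb`.
#' @export
simulate_map <- function(regimes, n_snps = 2000, anchors_per_cm = 2,
                         seed = 1L, chromosome = "1",
                         anchor_noise_cm = 0) {
  stopifnot(all(regimes$rate_cm_per_mb > 0), all(regimes$length_mb > 0))
  bp_breaks <- c(0, cumsum(regimes$length_mb)) * 1e6
  cm_breaks <- c(0, cumsum(regimes$length_mb * regimes$rate_cm_per_mb))
  total_mb <- sum(regimes$length_mb)
  total_cm <- cm_breaks[length(cm_breaks)]
  cm_of_bp <- function(bp) stats::approx(bp_breaks, cm_breaks, bp)$y
  bp_of_cm <- function(cm) stats::approx(cm_breaks, bp_breaks, cm)$y

  local_seed(seed, {
    pos <- sort(sample.int(total_mb * 1e6 - 1, n_snps))
    truth <- new_genetic_map(data.frame(
      snp_id = sprintf("snp%05d", seq_len(n_snps)),
      chromosome = chromosome, position_bp = pos,
      genetic_cm = cm_of_bp(pos), stringsAsFactors = FALSE), "truth")
    n_anchors <- max(2L, round(total_cm * anchors_per_cm))
    anc_cm <- seq(0, total_cm, length.out = n_anchors)
    anc_bp <- round(bp_of_cm(anc_cm))
    if (anchor_noise_cm > 0)
      anc_cm <- anc_cm + stats::rnorm(n_anchors, 0, anchor_noise_cm)
    anchors <- linkage_map(data.frame(
      snp_id = sprintf("anc%05d", seq_len(n_anchors)),
      chromosome = chromosome, position_bp = anc_bp,
      genetic_cm = anc_cm, stringsAsFactors = FALSE))
    list(truth = truth, anchors = anchors, total_cm = total_cm,
         total_mb = total_mb)
  })
}

#' Simulation configuration
#'
#' @param ne constant effective size, or a data frame with columns
#'   `generation` and `N`: piecewise-constant trajectory, most recent
#'   epoch first (row `(g, N)` means size `N` applied back to `g`
#'   generations ago).
#' @param n_chromosomes,chr_length_cm,n_snps genome layout; each
#'   chromosome carries `n_snps` SNPs on a `chr_length_cm` map.
#' @param maps optional list of per-chromosome dense `"genetic_map"`s
#'   giving SNP cM and bp positions (e.g. [simulate_map()]`$truth`);
#'   default: SNPs evenly spaced at 1 cM/Mb.
#' @param init_maf `"uniform"` draws initial allele frequencies from
#'   U(0.05, 0.5); a single number fixes them.
#' @param burnin burn-in generations at the oldest epoch's size
#'   (a warning is issued below 4x the maximum N).
#' @param sample_size diploid individuals genotyped from the final
#'   generation; when it exceeds the final epoch's N, the final cohort
#'   is expanded to `sample_size` offspring drawn from the N parents.
#' @param seed integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(ne = 100, n_chromosomes = 3, chr_length_cm = 100,
                       n_snps = 2000, maps = NULL, init_maf = "uniform",
                       burnin = NULL, sample_size = 200, seed = 1L) {
  traj <- if (is.data.frame(ne)) ne else
    data.frame(generation = Inf, N = ne)
  stopifnot(all(traj$N >= 2), sample_size >= 2)
  if (is.null(burnin)) burnin <- 4 * max(traj$N)
  if (burnin < 4 * max(traj$N))
    warning("burn-in below 4 x max(N); LD may not be at drift equilibrium")
  structure(list(ne_trajectory = traj, n_chromosomes = n_chromosomes,
                 chr_length_cm = chr_length_cm, n_snps = n_snps,
                 maps = maps, init_maf = init_maf, burnin = burnin,
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# one generation of gametes: H is (2N_parents x m) 0/1, parents indexes
# the chosen parent per gamete, snp_cm the SNP map positions (cM)
make_gametes <- function(H, parents, snp_cm, len_morgans) {
  G <- length(parents)
  m <- length(snp_cm)
  k <- stats::rpois(G, len_morgans)
  start <- sample.int(2L, G, replace = TRUE) - 1L
  out <- matrix(0L, G, m)
  none <- which(k == 0)
  if (length(none))
    out[none, ] <- H[2L * parents[none] - 1L + start[none], , drop = FALSE]
  for (g in which(k > 0)) {
    xo <- sort(stats::runif(k[g], 0, len_morgans * 100))
    seg <- findInterval(snp_cm, xo)
    sel <- (start[g] + seg) %% 2L
    rowA <- 2L * parents[g] - 1L
    hapA <- H[rowA, ]; hapB <- H[rowA + 1L, ]
    out[g, ] <- ifelse(sel == 0L, hapA, hapB)
  }
  out
}

#' Wright-Fisher forward simulation with recombination
#'
#' Discrete generations, random mating: each offspring draws two parents
#' uniformly from the previous generation; each transmitted gamete
#' recombines with a Poisson number of crossovers (Haldane model, no
#' interference) placed uniformly on the genetic map. Initial haplotypes
#' carry independent alleles at the configured frequencies; no mutation.
#' After the burn-in and the Ne trajectory, `sample_size` individuals
#' are sampled without replacement from the final cohort. Monomorphic
#' SNPs are retained (removing them is QC's job).
#'
#' @param config a [sim_config()].
#' @return List: `geno` (a [geno()] object), `haplotypes` (list per
#'   chromosome of sampled 2n x m haplotype matrices), `truth` (list:
#'   `map` dense `"genetic_map"`, `ne_trajectory`, `allele_freq`,
#'   `pedigree` of the final generation).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  K <- config$n_chromosomes
  m <- config$n_snps
  len_cm <- config$chr_length_cm
  if (is.null(config$maps)) {
    snp_cm <- lapply(seq_len(K), function(k)
      seq(0, len_cm, length.out = m))
    # bp at 1 cM/Mb, rescaled when the map is too long for integer bp
    bp_scale <- if (len_cm * 1e6 > 2e9) 2e9 / (len_cm * 1e6) else 1
    snp_bp <- lapply(snp_cm, function(cm)
      as.integer(round(cm * 1e6 * bp_scale) + seq_along(cm) - 1))
  } else {
    stopifnot(length(config$maps) == K)
    snp_cm <- lapply(config$maps, function(mp) mp$genetic_cm)
    snp_bp <- lapply(config$maps, function(mp) mp$position_bp)
  }
  len_morgans <- vapply(snp_cm, function(cm) max(cm) / 100, numeric(1))

  traj <- config$ne_trajectory
  # forward sequence of cohort sizes: burn-in at the oldest N, then
  # epochs oldest -> newest
  epochs <- traj[order(-traj$generation), ]
  gens <- rep(epochs$N[1], config$burnin)
  for (i in seq_len(nrow(epochs))) {
    gto <- if (i == nrow(epochs)) 1 else epochs$generation[i + 1] + 1
    gfrom <- min(epochs$generation[i], 10000)
    if (is.infinite(epochs$generation[i])) gfrom <- gto
    ngen <- max(0, gfrom - gto + 1)
    gens <- c(gens, rep(epochs$N[i], ngen))
  }
  if (length(gens) < 2) gens <- c(gens, gens[length(gens)])
  # final genotyped cohort can exceed the census of its parents
  gens[length(gens)] <- max(gens[length(gens)], config$sample_size)

  N0 <- gens[1]
  H <- vector("list", K)
  for (k in seq_len(K)) {
    p0 <- if (identical(config$init_maf, "uniform"))
      stats::runif(m, 0.05, 0.5) else rep(config$init_maf, m)
    H[[k]] <- matrix(stats::rbinom(2 * N0 * m, 1, rep(p0, each = 2 * N0)),
                     2 * N0, m)
    storage.mode(H[[k]]) <- "integer"
  }

  ped <- NULL
  nprev <- N0
  for (t in seq(2, length(gens))) {
    noff <- gens[t]
    p1 <- sample.int(nprev, noff, replace = TRUE)
    p2 <- sample.int(nprev, noff, replace = TRUE)
    for (k in seq_len(K)) {
      g1 <- make_gametes(H[[k]], p1, snp_cm[[k]], len_morgans[k])
      g2 <- make_gametes(H[[k]], p2, snp_cm[[k]], len_morgans[k])
      newH <- matrix(0L, 2 * noff, m)
      newH[seq(1, 2 * noff, by = 2), ] <- g1
      newH[seq(2, 2 * noff, by = 2), ] <- g2
      H[[k]] <- newH
    }
    nprev <- noff
    if (t == length(gens))
      ped <- data.frame(individual = seq_len(noff), parent1 = p1,
                        parent2 = p2)
  }

  take <- sample.int(nprev, config$sample_size)
  haplo <- lapply(H, function(h) {
    rows <- as.vector(rbind(2L * take - 1L, 2L * take))
    h[rows, , drop = FALSE]
  })
  dosage <- do.call(cbind, lapply(seq_len(K), function(k) {
    odd <- haplo[[k]][seq(1, nrow(haplo[[k]]), 2), , drop = FALSE]
    even <- haplo[[k]][seq(2, nrow(haplo[[k]]), 2), , drop = FALSE]
    odd + even
  }))
  snps <- do.call(rbind, lapply(seq_len(K), function(k)
    data.frame(snp_id = sprintf("c%d_s%04d", k, seq_len(m)),
               chromosome = as.character(k), position_bp = snp_bp[[k]],
               stringsAsFactors = FALSE)))
  animals <- data.frame(animal_id = sprintf("ind%04d", seq_along(take)),
                        sex = "unknown", stringsAsFactors = FALSE)
  gobj <- geno(dosage, snps, animals)
  true_map <- new_genetic_map(do.call(rbind, lapply(seq_len(K), function(k)
    data.frame(snp_id = sprintf("c%d_s%04d", k, seq_len(m)),
               chromosome = as.character(k), position_bp = snp_bp[[k]],
               genetic_cm = snp_cm[[k]], stringsAsFactors = FALSE))),
    "truth")
  freqs <- colMeans(dosage) / 2
  list(geno = gobj, haplotypes = haplo,
       truth = list(map = true_map, ne_trajectory = traj,
                    allele_freq = freqs,
                    pedigree = ped[take, , drop = FALSE]))
}

#' Corrupt a genotype object for QC testing
#'
#' Adds missing-completely-at-random calls, appends exact duplicate
#' animals (missingness applied independently afterwards), and
#' optionally appends X-chromosome SNPs whose heterozygosity is
#' consistent with each animal's recorded or assigned sex (females in
#' Hardy-Weinberg proportions; males homozygous apart from an error
#' rate).
#'
#' @param g a [geno()] object.
#' @param missing_rate MCAR missingness in `[0, 1)`.
#' @param duplicate_count number of animals to duplicate.
#' @param x_snps number of X-chromosome SNPs to append (0 = none).
#' @param x_error_rate male heterozygous-call error rate on X SNPs.
#' @param sexes optional sexes to assign (recycled); default: existing
#'   recorded sexes, or random when unknown.
#' @param seed integer seed.
#' @return List: `geno`, `manifest` (duplicate pairs, assigned sexes,
#'   rates).
#' @export
corrupt_geno <- function(g, missing_rate = 0, duplicate_count = 0,
                         x_snps = 0, x_error_rate = 0.005, sexes = NULL,
                         seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  local_seed(seed, {
    dosage <- g$dosage
    animals <- g$animals
    snps <- g$snps
    dup_pairs <- NULL
    if (duplicate_count > 0) {
      pick <- sample.int(nrow(dosage), duplicate_count)
      dup <- dosage[pick, , drop = FALSE]
      dup_ids <- paste0(animals$animal_id[pick], "_dup")
      dup_an <- animals[pick, , drop = FALSE]
      dup_an$animal_id <- dup_ids
      dosage <- rbind(dosage, dup)
      animals <- rbind(animals, dup_an)
      dup_pairs <- data.frame(original = g$animals$animal_id[pick],
                              duplicate = dup_ids,
                              stringsAsFactors = FALSE)
    }
    n <- nrow(dosage)
    if (is.null(sexes)) {
      sexes <- animals$sex
      unk <- sexes == "unknown"
      sexes[unk] <- sample(c("male", "female"), sum(unk), replace = TRUE)
    } else sexes <- rep_len(sexes, n)
    animals$sex <- sexes
    if (x_snps > 0) {
      p <- stats::runif(x_snps, 0.2, 0.5)
      xd <- matrix(NA_integer_, n, x_snps)
      for (i in seq_len(n)) {
        if (sexes[i] == "female") {
          xd[i, ] <- stats::rbinom(x_snps, 1, p) +
            stats::rbinom(x_snps, 1, p)
        } else {
          hom <- 2L * stats::rbinom(x_snps, 1, p)
          err <- stats::runif(x_snps) < x_error_rate
          hom[err] <- 1L
          xd[i, ] <- hom
        }
      }
      maxbp <- max(snps$position_bp)
      xsnps <- data.frame(snp_id = sprintf("x_s%04d", seq_len(x_snps)),
                          chromosome = "X",
                          position_bp = sort(sample.int(maxbp, x_snps)),
                          stringsAsFactors = FALSE)
      common <- intersect(names(snps), names(xsnps))
      snps <- rbind(snps[, common, drop = FALSE],
                    xsnps[, common, drop = FALSE])
      dosage <- cbind(dosage, xd)
    }
    if (missing_rate > 0) {
      mask <- matrix(stats::runif(length(dosage)) < missing_rate,
                     nrow(dosage))
      dosage[mask] <- NA_integer_
    }
    list(geno = geno(dosage, snps, animals),
         manifest = list(duplicates = dup_pairs,
                         missing_rate = missing_rate,
                         x_snps = x_snps, x_error_rate = x_error_rate,
                         sexes = sexes, seed = seed))
  })
}

#' Write a ready-made simulated dataset to disk
#'
#' Profiles: `"tiny"` (50 animals, 2 chromosomes x 250 SNPs, Ne 50) for
#' smoke tests; `"recovery"` (200 animals, 3 chromosomes x 2000 SNPs,
#' constant Ne 100, burn-in 400) for parameter-recovery checks. Emits
#' PLINK-style `.ped`/`.map` files, a breed-composition TSV, a sparse
#' linkage-map TSV derived from the true map, and a JSON truth manifest
#' echoing the seed and configuration.
#'
#' @param profile `"tiny"` or `"recovery"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Invisibly, a list with the simulation result and file paths.
#' @export
fixture_dataset <- function(profile = c("tiny", "recovery"), dir,
                            seed = 1L) {
  profile <- match.arg(profile)
  cfg <- if (profile == "tiny") {
    sim_config(ne = 50, n_chromosomes = 2, chr_length_cm = 100,
               n_snps = 250, burnin = 200, sample_size = 50, seed = seed)
  } else {
    sim_config(ne = 100, n_chromosomes = 3, chr_length_cm = 100,
               n_snps = 2000, burnin = 400, sample_size = 200,
               seed = seed)
  }
  sim <- simulate_population(cfg)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ped = file.path(dir, "genotypes.ped"),
                map = file.path(dir, "genotypes.map"),
                breeds = file.path(dir, "breeds.tsv"),
                linkage = file.path(dir, "linkage_map.tsv"),
                truth = file.path(dir, "truth.json"))
  write_ped_map(sim$geno, paths$ped, paths$map)
  bc <- data.frame(animal_id = sim$geno$animals$animal_id, Rom = 1)
  utils::write.table(bc, paths$breeds, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # sparse anchors: every 5th true-map SNP
  tm <- sim$truth$map
  anchors <- tm[seq(1, nrow(tm), by = 5), ]
  write_linkage_map(anchors, paths$linkage)
  jsonlite::write_json(list(profile = profile, seed = seed,
                            ne_trajectory = cfg$ne_trajectory,
                            n_chromosomes = cfg$n_chromosomes,
                            n_snps = cfg$n_snps,
                            chr_length_cm = cfg$chr_length_cm,
                            burnin = cfg$burnin,
                            sample_size = cfg$sample_size),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, paths = paths, config = cfg))
}
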