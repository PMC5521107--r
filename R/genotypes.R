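#' Genotype container for diploid bi-allelic SNP data
#'
#' Bundles a dosage matrix (animals in rows, SNPs in columns, values 0/1/2
#' with `NA` for a missing call; 1 is always the heterozygote) together with
#' SNP metadata (chromosome, physical position, alleles), animal metadata
#' (recorded sex, flock) and, optionally, per-animal breed-composition
#' proportions. SNPs are kept sorted by chromosome and physical position,
#' ties broken by SNP id.
#'
#' @param dosage integer matrix, animals x SNPs; `NA` = missing call.
#' @param snps data frame with columns `snp_id`, `chromosome`,
#'   `position_bp` and optionally `allele1`, `allele2`.
#' @param animals data frame with column `animal_id` and optionally
#'   `sex` (one of `"male"`, `"female"`, `"unknown"`) and `flock`.
#' @param breed_comp optional numeric matrix or data frame of breed
#'   proportions in `[0, 1]`, one row per animal, one column per breed
#'   label; row order must match `animals`.
#' @return An object of class `"geno"`.
#' @export
geno <- function(dosage, snps, animals = NULL, breed_comp = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chromosome", "position_bp") %in% names(snps)))
  if (nrow(snps) != ncol(dosage))
    stop("snps has ", nrow(snps), " rows but dosage has ", ncol(dosage),
         " columns")
  if (is.null(animals))
    animals <- data.frame(animal_id = if (is.null(rownames(dosage)))
      sprintf("A%d", seq_len(nrow(dosage))) else rownames(dosage),
      stringsAsFactors = FALSE)
  animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  stopifnot("animal_id" %in% names(animals))
  if (nrow(animals) != nrow(dosage))
    stop("animals has ", nrow(animals), " rows but dosage has ",
         nrow(dosage), " rows")
  if (!"sex" %in% names(animals)) animals$sex <- "unknown"
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(animals$animal_id))
    stop("duplicated animal_id values")
  if (anyDuplicated(snps$snp_id))
    stop("duplicated snp_id values")
  snps$chromosome <- as.character(snps$chromosome)
  snps$position_bp <- as.integer(snps$position_bp)
  if (any(snps$position_bp < 0, na.rm = TRUE))
    stop("position_bp must be non-negative")

  ord <- order(chrom_order(snps$chromosome), snps$position_bp, snps$snp_id)
  snps <- snps[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  rownames(snps) <- NULL
  dimnames(dosage) <- list(animals$animal_id, snps$snp_id)

  if (!is.null(breed_comp)) {
    breed_comp <- as.matrix(as.data.frame(breed_comp))
    storage.mode(breed_comp) <- "double"
    if (nrow(breed_comp) != nrow(dosage))
      stop("breed_comp row count does not match animals")
    rownames(breed_comp) <- animals$animal_id
    if (any(breed_comp < 0 | breed_comp > 1, na.rm = TRUE))
      stop("breed proportions must lie in [0, 1]")
  }
  structure(list(dosage = dosage, snps = snps, animals = animals,
                 breed_comp = breed_comp),
            class = "geno")
}

# sort key placing autosomes 1..n numerically, then named chromosomes (X, ...)
chrom_order <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  key <- ifelse(is.na(num), 1e6 + as.numeric(factor(chr)), num)
  key
}

#' @export
dim.geno <- function(x) dim(x$dosage)

#' @export
print.geno <- function(x, ...) {
  cat("Genotypes:", nrow(x$dosage), "animals x", ncol(x$dosage), "SNPs\n")
  tab <- table(x$snps$chromosome)
  cat("Chromosomes:", paste0(names(tab), " (", tab, ")", collapse = ", "),
      "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("Missing calls: %.2f%%\n", 100 * miss))
  if (!is.null(x$breed_comp))
    cat("Breed composition columns:",
        paste(colnames(x$breed_comp), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype object by animals and/or SNPs
#'
#' @param g a [geno()] object.
#' @param animals logical/integer/character index into animals.
#' @param snps logical/integer/character index into SNPs.
#' @return A `"geno"` object.
#' @export
subset_geno <- function(g, animals = NULL, snps = NULL) {
  stopifnot(inherits(g, "geno"))
  ai <- if (is.null(animals)) seq_len(nrow(g$dosage)) else animals
  if (is.character(ai)) ai <- match(ai, g$animals$animal_id)
  si <- if (is.null(snps)) seq_len(ncol(g$dosage)) else snps
  if (is.character(si)) si <- match(si, g$snps$snp_id)
  geno(g$dosage[ai, si, drop = FALSE],
       g$snps[si, , drop = FALSE],
       g$animals[ai, , drop = FALSE],
       if (!is.null(g$breed_comp)) g$breed_comp[ai, , drop = FALSE])
}

#' Indices of autosomal SNPs
#'
#' Autosomes are chromosome labels that parse as numbers; anything else
#' (X, Y, MT, simulated labels containing letters) is non-autosomal.
#'
#' @param g a [geno()] object.
#' @return Integer vector of SNP column indices.
#' @export
autosomal_snps <- function(g) {
  which(!is.na(suppressWarnings(as.numeric(g$snps$chromosome))))
}

#' Read PLINK-style .ped/.map genotype files
#'
#' The `.map` file has four whitespace-separated columns (chromosome,
#' snp_id, genetic position, physical bp position); the `.ped` file has six
#' leading columns (family, individual, sire, dam, sex, phenotype) followed
#' by two allele columns per SNP. `0` codes a missing allele. Dosages are
#' coded as the count of the second listed allele for each SNP (order of
#' first appearance down the file). A `.ped` whose genotype block has one
#' column per SNP with values in 0/1/2/NA is accepted as a dosage coding.
#'
#' @param ped,map paths to the two files.
#' @return A [geno()] object; sire/dam/family columns are passed through on
#'   the animal table.
#' @export
read_ped_map <- function(ped, map) {
  mp <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(mp) < 4) stop("map file must have 4 columns")
  names(mp)[1:4] <- c("chromosome", "snp_id", "genetic", "position_bp")
  pd <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  n_snp <- nrow(mp)
  gcols <- ncol(pd) - 6L
  if (gcols == n_snp) {
    block <- as.matrix(pd[, -(1:6), drop = FALSE])
    suppressWarnings(storage.mode(block) <- "integer")
    dosage <- block
    a1 <- rep(NA_character_, n_snp); a2 <- rep(NA_character_, n_snp)
  } else if (gcols == 2L * n_snp) {
    block <- as.matrix(pd[, -(1:6), drop = FALSE])
    al1 <- block[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
    al2 <- block[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
    al1[al1 == "0"] <- NA; al2[al2 == "0"] <- NA
    # half-missing genotypes are treated as missing calls
    half <- is.na(al1) != is.na(al2)
    al1[half] <- NA; al2[half] <- NA
    dosage <- matrix(NA_integer_, nrow(pd), n_snp)
    a1 <- a2 <- rep(NA_character_, n_snp)
    for (j in seq_len(n_snp)) {
      obs <- c(rbind(al1[, j], al2[, j]))
      alleles <- unique(obs[!is.na(obs)])
      if (length(alleles) > 2)
        stop("SNP ", mp$snp_id[j], " has more than two alleles")
      a1[j] <- if (length(alleles) >= 1) alleles[1] else NA_character_
      a2[j] <- if (length(alleles) == 2) alleles[2] else NA_character_
      d <- (al1[, j] == a2[j]) + (al2[, j] == a2[j])
      if (is.na(a2[j])) d <- ifelse(is.na(al1[, j]), NA_integer_, 0L)
      dosage[, j] <- as.integer(d)
    }
  } else {
    stop("format error: .map lists ", n_snp, " SNPs but .ped rows carry ",
         gcols, " genotype columns (line 1)")
  }
  sexcode <- c("1" = "male", "2" = "female")
  animals <- data.frame(
    animal_id = pd[[2]], family = pd[[1]], sire = pd[[3]], dam = pd[[4]],
    sex = ifelse(pd[[5]] %in% names(sexcode), sexcode[pd[[5]]], "unknown"),
    stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = as.character(mp$snp_id),
                     chromosome = as.character(mp$chromosome),
                     position_bp = as.integer(mp$position_bp),
                     allele1 = a1, allele2 = a2, stringsAsFactors = FALSE)
  geno(dosage, snps, animals)
}

#' Write PLINK-style .ped/.map files
#'
#' @param g a [geno()] object.
#' @param ped,map output paths.
#' @export
write_ped_map <- function(g, ped, map) {
  stopifnot(inherits(g, "geno"))
  mp <- data.frame(g$snps$chromosome, g$snps$snp_id, 0,
                   g$snps$position_bp)
  utils::write.table(mp, map, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  a1 <- g$snps$allele1; a2 <- g$snps$allele2
  if (is.null(a1) || all(is.na(a1))) a1 <- rep("A", ncol(g$dosage))
  if (is.null(a2) || all(is.na(a2))) a2 <- rep("B", ncol(g$dosage))
  a2[is.na(a2)] <- "B"; a1[is.na(a1)] <- "A"
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  out <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    d <- g$dosage[, j]
    l1 <- ifelse(is.na(d), "0", ifelse(d >= 1, a2[j], a1[j]))
    l2 <- ifelse(is.na(d), "0", ifelse(d == 2, a2[j], a1[j]))
    out[, 2 * j - 1] <- l1; out[, 2 * j] <- l2
  }
  an <- g$animals
  fam <- if ("family" %in% names(an)) an$family else an$animal_id
  sire <- if ("sire" %in% names(an)) an$sire else "0"
  dam <- if ("dam" %in% names(an)) an$dam else "0"
  sex <- match(an$sex, c("male", "female"))
  sex[is.na(sex)] <- 0
  lead <- cbind(fam, an$animal_id, sire, dam, sex, -9)
  utils::write.table(cbind(lead, out), ped, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
}

#' Read/write a plain genotype table
#'
#' The table dialect is tab-separated with a header row: first column
#' `animal_id`, remaining columns one per SNP holding integer dosages with
#' missing coded `NA`. SNP metadata travels in a companion map table
#' (`snp_id`, `chromosome`, `position_bp`).
#'
#' @param table,map paths to the genotype table and SNP map TSVs.
#' @return A [geno()] object.
#' @export
read_geno_table <- function(table, map) {
  gt <- utils::read.table(table, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  mp <- utils::read.table(map, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  dosage <- as.matrix(gt[, -1, drop = FALSE])
  if (!setequal(colnames(dosage), mp$snp_id))
    stop("format error: table SNP columns do not match the map")
  mp <- mp[match(colnames(dosage), mp$snp_id), ]
  geno(dosage, mp, data.frame(animal_id = gt[[1]],
                              stringsAsFactors = FALSE))
}

#' @rdname read_geno_table
#' @param g a [geno()] object to write.
#' @export
write_geno_table <- function(g, table, map) {
  stopifnot(inherits(g, "geno"))
  df <- data.frame(animal_id = g$animals$animal_id, g$dosage,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, table, quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(g$snps[, c("snp_id", "chromosome", "position_bp")],
                     map, quote = FALSE, sep = "\t", row.names = FALSE)
}

#' Read a breed-composition table
#'
#' TSV with header: `animal_id` then one numeric column per breed label.
#'
#' @param path file path.
#' @param g optional [geno()] object; if given, rows are matched and the
#'   composition is attached to a copy of `g`.
#' @return A data frame, or `g` with `breed_comp` filled in.
#' @export
read_breed_comp <- function(path, g = NULL) {
  bc <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(g)) return(bc)
  idx <- match(g$animals$animal_id, bc$animal_id)
  if (anyNA(idx)) stop("breed composition missing for some animals")
  g$breed_comp <- as.matrix(bc[idx, -1, drop = FALSE])
  rownames(g$breed_comp) <- g$animals$animal_id
  g
}
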