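#' IMF sheep linkage-map chromosome summary
#'
#' Per-chromosome summary of the 6448-SNP sex-averaged linkage map
#' estimated on the International Mapping Flock (IMF) against Ovine
#' Genome v3.1: physical size in Mb (last SNP position), number of map
#' SNPs, the earlier microsatellite-based genetic length (`maddox_cm`),
#' the SNP-based genetic length (`genetic_cm`) and the published cM/Mb
#' ratio (`ratio`, two decimals, computed from unrounded genetic
#' lengths). Totals: 2439 Mb, 6448 SNPs, 3403 / 3421 cM; the genome-wide
#' mean of the per-chromosome ratios is 1.51 and the correlation of
#' physical size with the ratio is -0.70.
#'
#' @format Data frame with 26 rows and 6 columns: `chromosome`,
#'   `physical_mb`, `n_snps`, `maddox_cm`, `genetic_cm`, `ratio`.
#' @export
imf_chromosome_summary <- data.frame(
  chromosome = paste0("OAR", 1:26),
  physical_mb = c(275, 249, 224, 119, 107, 116, 100, 90, 94, 86, 62, 77,
                  83, 62, 80, 71, 72, 69, 60, 51, 49, 50, 62, 42, 45, 44),
  n_snps = c(675, 598, 575, 321, 285, 303, 281, 243, 261, 202, 173, 206,
             241, 167, 190, 205, 196, 187, 177, 159, 113, 149, 160, 113,
             133, 135),
  maddox_cm = c(341, 308, 321, 129, 153, 155, 134, 125, 126, 100, 119, 94,
                132, 116, 109, 81, 121, 120, 75, 81, 74, 85, 76, 89, 69,
                70),
  genetic_cm = c(323, 292, 273, 155, 152, 144, 137, 124, 126, 116, 110,
                 112, 130, 118, 110, 87, 114, 115, 108, 86, 79, 83, 90,
                 84, 77, 76),
  ratio = c(1.17, 1.17, 1.22, 1.30, 1.43, 1.24, 1.37, 1.38, 1.34, 1.34,
            1.78, 1.45, 1.56, 1.90, 1.37, 1.22, 1.59, 1.68, 1.81, 1.70,
            1.60, 1.67, 1.45, 2.01, 1.72, 1.75),
  stringsAsFactors = FALSE)
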