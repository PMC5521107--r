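#' Sparse linkage map
#'
#' Validates a data frame of linkage-map anchors: columns `snp_id`,
#' `chromosome`, `position_bp`, `genetic_cm` (cumulative sex-averaged
#' Kosambi positions per chromosome). Rows are sorted by chromosome and
#' physical position.
#'
#' @param df a data frame with the four columns above.
#' @return The sorted data frame with class `"linkage_map"`.
#' @export
linkage_map <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("snp_id", "chromosome", "position_bp", "genetic_cm")
                %in% names(df)))
  df$chromosome <- as.character(df$chromosome)
  ord <- order(chrom_order(df$chromosome), df$position_bp, df$snp_id)
  df <- df[ord, c("snp_id", "chromosome", "position_bp", "genetic_cm")]
  for (chr in unique(df$chromosome)) {
    pos <- df$position_bp[df$chromosome == chr]
    if (any(duplicated(pos)))
      stop("duplicated physical positions on chromosome ", chr)
  }
  rownames(df) <- NULL
  class(df) <- c("linkage_map", "data.frame")
  df
}

#' @rdname linkage_map
#' @param path TSV file with header columns `snp_id`, `chromosome`,
#'   `position_bp`, `genetic_cm`.
#' @export
read_linkage_map <- function(path) {
  linkage_map(utils::read.table(path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE))
}

#' @rdname linkage_map
#' @param map a `"linkage_map"` or dense `"genetic_map"`.
#' @export
write_linkage_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("snp_id", "chromosome",
                                            "position_bp", "genetic_cm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

new_genetic_map <- function(df, method) {
  df <- df[, c("snp_id", "chromosome", "position_bp", "genetic_cm")]
  rownames(df) <- NULL
  attr(df, "method") <- method
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' M1: constant genome-wide cM/Mb conversion
#'
#' Genetic position = physical position (Mb) times a single genome-wide
#' ratio (the conventional 1 cM/Mb by default; the mean per-chromosome
#' ratio of a linkage map, e.g. 1.51, is a useful alternative).
#'
#' @param snps data frame (or [geno()] object) with `snp_id`,
#'   `chromosome`, `position_bp`.
#' @param genome_ratio cM per Mb, > 0.
#' @return A dense `"genetic_map"` data frame.
#' @export
m1_positions <- function(snps, genome_ratio = 1) {
  stopifnot(genome_ratio > 0)
  snps <- snp_table(snps)
  snps$genetic_cm <- snps$position_bp / 1e6 * genome_ratio
  new_genetic_map(snps, "M1")
}

snp_table <- function(x) {
  if (inherits(x, "geno")) x <- x$snps
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  x[order(chrom_order(x$chromosome), x$position_bp, x$snp_id),
    c("snp_id", "chromosome", "position_bp")]
}

#' Per-chromosome cM/Mb ratios from a linkage map
#'
#' Ratio = total genetic length of the chromosome on the linkage map
#' (last minus first cumulative cM) divided by its physical length in Mb.
#' Physical lengths default to the last linkage-map anchor position; pass
#' the chip's last-SNP positions to follow the convention that chromosome
#' size is the last chip SNP position.
#'
#' @param linkage a [linkage_map()].
#' @param physical_mb optional named vector of chromosome lengths in Mb.
#' @return Named vector of ratios (cM/Mb).
#' @export
chromosome_ratios <- function(linkage, physical_mb = NULL) {
  chrs <- unique(linkage$chromosome)
  if (!is.null(physical_mb)) {
    miss <- setdiff(names(physical_mb), chrs)
    if (length(miss))
      stop("chromosome(s) absent from the linkage map: ",
           paste(miss, collapse = ", "))
    chrs <- names(physical_mb)
  }
  out <- vapply(chrs, function(chr) {
    cm <- linkage$genetic_cm[linkage$chromosome == chr]
    if (!length(cm))
      stop("chromosome ", chr, " absent from the linkage map")
    len_cm <- max(cm) - min(cm)
    mb <- if (is.null(physical_mb)) {
      max(linkage$position_bp[linkage$chromosome == chr]) / 1e6
    } else physical_mb[[chr]]
    stopifnot(mb > 0)
    len_cm / mb
  }, numeric(1))
  names(out) <- chrs
  out
}

#' M2: chromosome-specific cM/Mb conversion
#'
#' @param snps data frame (or [geno()]) with `snp_id`, `chromosome`,
#'   `position_bp`.
#' @param ratios named vector of per-chromosome cM/Mb ratios, e.g. from
#'   [chromosome_ratios()].
#' @return A dense `"genetic_map"`.
#' @export
m2_positions <- function(snps, ratios) {
  snps <- snp_table(snps)
  miss <- setdiff(unique(snps$chromosome), names(ratios))
  if (length(miss))
    stop("no ratio for chromosome(s): ", paste(miss, collapse = ", "))
  snps$genetic_cm <- snps$position_bp / 1e6 * ratios[snps$chromosome]
  new_genetic_map(snps, "M2")
}

#' Consecutive-anchor intervals with trimming mask
#'
#' Computes, for every pair of consecutive linkage-map anchors, the
#' physical and genetic interval lengths and their ratio, then marks for
#' removal (a) intervals with negative delta-cM, which imply an
#' alternative marker order, and (b) intervals whose ratio reaches the
#' genome-wide 99.9th percentile (type-7 empirical quantile, removal iff
#' ratio >= the quantile), which are treated as assembly artefacts.
#'
#' @param linkage a [linkage_map()].
#' @param trim_quantile percentile for the extreme-ratio rule.
#' @return Data frame of class `"map_intervals"`: `chromosome`,
#'   `start_bp`, `end_bp`, `delta_cm`, `delta_mb`, `ratio`, `removed`,
#'   `reason`.
#' @export
interval_ratios <- function(linkage, trim_quantile = 0.999) {
  out <- NULL
  for (chr in unique(linkage$chromosome)) {
    sub <- linkage[linkage$chromosome == chr, ]
    if (nrow(sub) < 2) next
    out <- rbind(out, data.frame(
      chromosome = chr,
      start_bp = sub$position_bp[-nrow(sub)],
      end_bp = sub$position_bp[-1],
      delta_cm = diff(sub$genetic_cm),
      delta_mb = diff(sub$position_bp) / 1e6,
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) stop("need at least 2 anchors on some chromosome")
  out$ratio <- out$delta_cm / out$delta_mb
  q <- stats::quantile(out$ratio, trim_quantile, type = 7, names = FALSE)
  out$reason <- ""
  # an extreme interval must also exceed the typical ratio, so that a
  # uniform map (every interval tied at the quantile) loses nothing
  out$reason[out$ratio >= q &
               out$ratio > stats::median(out$ratio)] <- "extreme_ratio"
  out$reason[out$delta_cm < 0] <- "negative_cm"
  out$removed <- out$reason != ""
  class(out) <- c("map_intervals", "data.frame")
  out
}

# rebuild cumulative anchor positions after interval trimming: removed
# intervals contribute zero recombination, keeping every anchor addressable
trimmed_anchor_positions <- function(linkage, intervals) {
  lk <- linkage
  lk$genetic_adj <- NA_real_
  for (chr in unique(lk$chromosome)) {
    rows <- which(lk$chromosome == chr)
    iv <- intervals[intervals$chromosome == chr, ]
    d <- iv$delta_cm
    d[iv$removed] <- 0
    lk$genetic_adj[rows] <- cumsum(c(0, d))
  }
  lk
}

#' M3: local-polynomial interpolation of a sparse linkage map
#'
#' Per chromosome: extreme and negative intervals of the linkage map are
#' trimmed ([interval_ratios()]), anchor positions are rebuilt with
#' trimmed intervals collapsed to zero recombination, a loess regression
#' of genetic position (cM) on physical position (Mb) is fitted on the
#' surviving anchors, and genetic positions are predicted for every chip
#' SNP. Predictions are clamped non-decreasing (running maximum) and
#' non-negative. Chip SNPs beyond the anchor range are extended linearly
#' at the chromosome's M2 ratio. Chromosomes with fewer than
#' `min_anchors` anchors fall back to M2 with a warning.
#'
#' @param linkage a [linkage_map()].
#' @param snps chip SNP table (or [geno()]).
#' @param span,degree loess settings (local quadratic, span 0.3 by
#'   default).
#' @param min_anchors minimum anchors per chromosome before falling back.
#' @param trim_quantile passed to [interval_ratios()].
#' @return A dense `"genetic_map"`.
#' @export
m3_positions <- function(linkage, snps, span = 0.3, degree = 2,
                         min_anchors = 10, trim_quantile = 0.999) {
  snps <- snp_table(snps)
  intervals <- interval_ratios(linkage, trim_quantile)
  lk <- trimmed_anchor_positions(linkage, intervals)
  ratios <- chromosome_ratios(linkage)
  out_cm <- rep(NA_real_, nrow(snps))
  for (chr in unique(snps$chromosome)) {
    rows <- which(snps$chromosome == chr)
    x <- snps$position_bp[rows] / 1e6
    anc <- lk[lk$chromosome == chr, ]
    if (nrow(anc) < min_anchors) {
      warning("chromosome ", chr, ": only ", nrow(anc),
              " anchors; falling back to M2")
      r <- if (chr %in% names(ratios)) ratios[[chr]] else 1
      out_cm[rows] <- x * r
      next
    }
    ax <- anc$position_bp / 1e6
    ay <- anc$genetic_adj
    # span floor so the local window always holds enough anchors
    eff_span <- max(span, min(1, (degree + 2) / nrow(anc) * 3))
    fit <- stats::loess(ay ~ ax, span = eff_span, degree = degree,
                        control = stats::loess.control(surface = "direct"))
    inside <- x >= min(ax) & x <= max(ax)
    pred <- rep(NA_real_, length(x))
    if (any(inside)) pred[inside] <- stats::predict(fit,
                                                    data.frame(ax = x[inside]))
    r <- ratios[[chr]]
    lo <- stats::predict(fit, data.frame(ax = min(ax)))
    hi <- stats::predict(fit, data.frame(ax = max(ax)))
    pred[x < min(ax)] <- lo - (min(ax) - x[x < min(ax)]) * r
    pred[x > max(ax)] <- hi + (x[x > max(ax)] - max(ax)) * r
    pred <- cummax(pmax(pred, 0))
    out_cm[rows] <- unname(pred)
  }
  snps$genetic_cm <- out_cm
  new_genetic_map(snps, "M3")
}

#' Recombination-rate track of a dense map
#'
#' Delta-cM / delta-Mb for every consecutive chip-SNP interval.
#'
#' @param dense a `"genetic_map"`.
#' @return Data frame: `chromosome`, `start_bp`, `end_bp`, `ratio`.
#' @export
recombination_profile <- function(dense) {
  out <- NULL
  for (chr in unique(dense$chromosome)) {
    sub <- dense[dense$chromosome == chr, ]
    if (nrow(sub) < 2) next
    out <- rbind(out, data.frame(
      chromosome = chr,
      start_bp = sub$position_bp[-nrow(sub)],
      end_bp = sub$position_bp[-1],
      ratio = diff(sub$genetic_cm) / (diff(sub$position_bp) / 1e6),
      stringsAsFactors = FALSE))
  }
  out
}

#' Chromosome summary table and length-ratio correlation
#'
#' One row per chromosome: physical size in Mb (the last chip-SNP
#' position), number of linkage-map SNPs, total genetic length in cM and
#' the cM/Mb ratio; plus a TOTAL row (sums; ratio = unweighted mean of
#' the per-chromosome ratios). The Pearson correlation of physical length
#' with the ratio and its two-sided t-test p-value are attached; with
#' zero ratio variance the correlation is reported as `NA`.
#'
#' @param linkage a [linkage_map()].
#' @param chip chip SNP table (or [geno()]) giving last-SNP positions;
#'   defaults to the linkage map itself.
#' @return Data frame with attributes `correlation` and `p_value`.
#' @export
map_summary <- function(linkage, chip = NULL) {
  chip <- if (is.null(chip)) linkage else snp_table(chip)
  chrs <- unique(linkage$chromosome)
  rows <- lapply(chrs, function(chr) {
    anc <- linkage[linkage$chromosome == chr, ]
    mb <- max(chip$position_bp[chip$chromosome == chr]) / 1e6
    cm <- max(anc$genetic_cm) - min(anc$genetic_cm)
    data.frame(chromosome = chr, physical_mb = mb, n_snps = nrow(anc),
               genetic_cm = cm, ratio = cm / mb, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  summary_stats_from_table(tab)
}

#' Summary statistics from a chromosome-summary table
#'
#' Appends the TOTAL row and attaches the length-ratio correlation to a
#' prebuilt table with columns `chromosome`, `physical_mb`, `n_snps`,
#' `genetic_cm`, `ratio` (e.g. [imf_chromosome_summary]).
#'
#' @param tab the per-chromosome table (no TOTAL row).
#' @return The table with a TOTAL row and attributes `correlation`,
#'   `p_value`, `mean_ratio`.
#' @export
summary_stats_from_table <- function(tab) {
  tab <- tab[tab$chromosome != "TOTAL", ]
  if (nrow(tab) >= 3 && stats::sd(tab$ratio) > 0) {
    ct <- stats::cor.test(tab$physical_mb, tab$ratio)
    corr <- unname(ct$estimate); pv <- ct$p.value
  } else {
    corr <- NA_real_; pv <- NA_real_
  }
  total <- tab[1, , drop = FALSE]
  for (col in names(total)) {
    total[[col]] <- if (col == "chromosome") "TOTAL" else
      if (col == "ratio") mean(tab[[col]]) else sum(tab[[col]])
  }
  out <- rbind(tab, total)
  rownames(out) <- NULL
  attr(out, "correlation") <- corr
  attr(out, "p_value") <- pv
  attr(out, "mean_ratio") <- total$ratio
  out
}

#' Kosambi map function and its inverse
#'
#' `kosambi_r` converts genetic distance (cM) to recombination fraction,
#' `r = 0.5 tanh(2d)` with `d` in Morgans; `kosambi_cm` inverts it,
#' `d = 0.25 log((1 + 2r) / (1 - 2r))`.
#'
#' @param cm genetic distance in centiMorgans (>= 0).
#' @param r recombination fraction in `[0, 0.5)`.
#' @return Recombination fraction, or distance in cM.
#' @export
kosambi_r <- function(cm) {
  stopifnot(all(cm >= 0))
  0.5 * tanh(2 * cm / 100)
}

#' @rdname kosambi_r
#' @export
kosambi_cm <- function(r) {
  stopifnot(all(r >= 0 & r < 0.5))
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Write a UCSC custom-track file
#'
#' Four tab-separated columns after a `track` header line: chromosome,
#' physical position of the previous marker, physical position of the
#' marker, and the value (genetic position in cM for a map track, the
#' interval cM/Mb ratio for a rate track).
#'
#' @param x a dense `"genetic_map"` or a [recombination_profile()] data
#'   frame.
#' @param path output path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
write_ucsc_track <- function(x, path, name = "genetic_map") {
  if (inherits(x, "genetic_map")) {
    rows <- NULL
    for (chr in unique(x$chromosome)) {
      sub <- x[x$chromosome == chr, ]
      if (nrow(sub) < 2) next
      rows <- rbind(rows, data.frame(
        chromosome = chr, prev_bp = sub$position_bp[-nrow(sub)],
        pos_bp = sub$position_bp[-1], value = sub$genetic_cm[-1],
        stringsAsFactors = FALSE))
    }
  } else {
    rows <- data.frame(chromosome = x$chromosome, prev_bp = x$start_bp,
                       pos_bp = x$end_bp, value = x$ratio,
                       stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track name="%s" type=bedGraph', name), con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ucsc_track
#' @export
read_ucsc_track <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "track"))
    stop("not a UCSC custom-track file (no 'track' header line)")
  df <- utils::read.table(text = lines[-1], sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- c("chromosome", "prev_bp", "pos_bp", "value")
  df
}
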