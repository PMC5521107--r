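#' Pairwise r-squared between two SNPs
#'
#' The default (composite) estimator is the squared Pearson correlation
#' of the two dosage vectors over pairwise-complete animals, which
#' operates directly on unphased genotypes. For phased haplotype data the
#' classical haplotype-frequency form
#' `r2 = (f(AB) - f(A) f(B))^2 / (f(A) f(a) f(B) f(b))`
#' is available via [r2_haplotype()], and an EM haplotype-frequency
#' estimator for unphased data via [r2_em()].
#'
#' @param a,b dosage vectors (0/1/2, `NA` missing) of equal length.
#' @return r-squared in `[0, 1]`, or `NA` when fewer than two
#'   pairwise-complete animals remain or either SNP is monomorphic in the
#'   pairwise-complete subset.
#' @export
pairwise_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 || vb == 0) return(NA_real_)
  stats::cov(a, b)^2 / (va * vb)
}

#' @rdname pairwise_r2
#' @param hap_a,hap_b phased haplotype vectors of 0/1 allele indicators
#'   (one entry per haplotype).
#' @export
r2_haplotype <- function(hap_a, hap_b) {
  ok <- !is.na(hap_a) & !is.na(hap_b)
  hap_a <- hap_a[ok]; hap_b <- hap_b[ok]
  fA <- mean(hap_a); fB <- mean(hap_b)
  if (fA %in% c(0, 1) || fB %in% c(0, 1)) return(NA_real_)
  fAB <- mean(hap_a * hap_b)
  D <- fAB - fA * fB
  D^2 / (fA * (1 - fA) * fB * (1 - fB))
}

#' @rdname pairwise_r2
#' @param max_iter,tol EM controls.
#' @export
r2_em <- function(a, b, max_iter = 100, tol = 1e-8) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2) return(NA_real_)
  pA <- mean(a) / 2; pB <- mean(b) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NA_real_)
  # haplotype frequencies (AB, Ab, aB, ab); only double heterozygotes are
  # phase-ambiguous
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  dh <- sum(a == 1 & b == 1)
  # fixed haplotype counts from phase-unambiguous genotypes
  cnt_fixed <- function() {
    c(AB = 2 * sum(a == 2 & b == 2) + sum(a == 2 & b == 1) +
        sum(a == 1 & b == 2),
      Ab = 2 * sum(a == 2 & b == 0) + sum(a == 2 & b == 1) +
        sum(a == 1 & b == 0),
      aB = 2 * sum(a == 0 & b == 2) + sum(a == 0 & b == 1) +
        sum(a == 1 & b == 2),
      ab = 2 * sum(a == 0 & b == 0) + sum(a == 0 & b == 1) +
        sum(a == 1 & b == 0))
  }
  fixed <- cnt_fixed()
  for (it in seq_len(max_iter)) {
    # split double heterozygotes between AB/ab and Ab/aB phases
    pcis <- f[1] * f[4]
    ptrans <- f[2] * f[3]
    w <- if (pcis + ptrans > 0) pcis / (pcis + ptrans) else 0.5
    cnt <- fixed + c(dh * w, dh * (1 - w), dh * (1 - w), dh * w)
    fnew <- cnt / (2 * n)
    if (max(abs(fnew - f)) < tol) { f <- fnew; break }
    f <- fnew
  }
  fA <- f[1] + f[2]; fB <- f[1] + f[3]
  D <- f[1] - fA * fB
  unname(D^2 / (fA * (1 - fA) * fB * (1 - fB)))
}

# vectorized composite r2 for many pairs, pairwise-complete handling
r2_pairs <- function(dosage, ia, ib, chunk = 5000L) {
  out <- numeric(length(ia))
  for (s in seq(1, length(ia), by = chunk)) {
    e <- min(s + chunk - 1L, length(ia))
    A <- dosage[, ia[s:e], drop = FALSE]
    B <- dosage[, ib[s:e], drop = FALSE]
    M <- (!is.na(A)) & (!is.na(B))
    A[!M] <- 0; B[!M] <- 0
    storage.mode(A) <- "double"; storage.mode(B) <- "double"
    n <- colSums(M)
    sa <- colSums(A); sb <- colSums(B)
    saa <- colSums(A * A); sbb <- colSums(B * B)
    sab <- colSums(A * B)
    va <- n * saa - sa^2
    vb <- n * sbb - sb^2
    num <- (n * sab - sa * sb)^2
    r2 <- num / (va * vb)
    r2[n < 2 | va <= 0 | vb <= 0] <- NA_real_
    out[s:e] <- r2
  }
  out
}

#' Sample marker pairs on a chromosome and compute their r-squared
#'
#' Draws `n_pairs` distinct unordered SNP pairs uniformly without
#' replacement from all same-chromosome pairs (all of them when fewer
#' exist), annotates each with the genetic distance under the supplied
#' dense map, and computes the composite r-squared. Pairs with undefined
#' r-squared are dropped; their count is kept in attribute
#' `"n_dropped"`.
#'
#' @param g a [geno()] object.
#' @param chromosome chromosome label.
#' @param dense_map a `"genetic_map"` covering the chromosome's SNPs.
#' @param n_pairs number of pairs to draw.
#' @param seed integer seed for the draw.
#' @return Data frame: `snp_a`, `snp_b`, `distance_cm`, `r2`.
#' @export
sample_pairs <- function(g, chromosome, dense_map, n_pairs = 20000,
                         seed = 1L) {
  idx <- which(g$snps$chromosome == chromosome)
  m <- length(idx)
  if (m < 2) stop("chromosome ", chromosome, " has fewer than 2 SNPs")
  total <- m * (m - 1) / 2
  take <- min(n_pairs, total)
  sel <- if (take == total) seq_len(total) else
    local_seed(seed, sample(total, take))
  # map linear index k in 1..m(m-1)/2 to pair (i < j), column-major over j
  j <- ceiling((1 + sqrt(1 + 8 * sel)) / 2)
  i <- sel - (j - 1) * (j - 2) / 2
  ia <- idx[i]; ib <- idx[j]
  cm <- dense_map$genetic_cm[match(g$snps$snp_id, dense_map$snp_id)]
  dist <- abs(cm[ia] - cm[ib])
  r2 <- r2_pairs(g$dosage, ia, ib)
  keep <- !is.na(r2)
  out <- data.frame(snp_a = g$snps$snp_id[ia][keep],
                    snp_b = g$snps$snp_id[ib][keep],
                    distance_cm = dist[keep], r2 = r2[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit an LD-decay curve on a genetic-distance grid
#'
#' Local-polynomial (loess, tricube weights) regression of pairwise
#' r-squared on genetic distance, evaluated at the grid values;
#' predictions are clamped to `[0, 1]`. Pairs outside the grid range
#' still inform the fit near the boundaries. The default is a local
#' quadratic with a narrow span (0.05): the decay curve is hyperbolic,
#' and wide windows or local-linear fits inflate the short-distance end
#' of the curve (and thereby deflate recent-generation Ne) through
#' curvature bias. The span is floored so a window never holds fewer
#' than about 40 pairs.
#'
#' @param distance_cm,r2 pair observations.
#' @param grid_cm evaluation grid.
#' @param span loess span.
#' @param degree local polynomial degree (1 or 2).
#' @param min_pairs minimum number of pairs with distance inside the
#'   grid range; below it the fit is refused (returns all-`NA`).
#' @return Numeric vector of expected r-squared at `grid_cm`.
#' @export
fit_decay <- function(distance_cm, r2, grid_cm, span = 0.05, degree = 2,
                      min_pairs = 50) {
  rng <- range(grid_cm)
  inside <- sum(distance_cm >= rng[1] & distance_cm <= rng[2])
  if (inside < min_pairs) return(rep(NA_real_, length(grid_cm)))
  eff_span <- max(span, min(1, 40 / length(distance_cm)))
  fit <- stats::loess(r2 ~ distance_cm, span = eff_span, degree = degree,
                      family = "gaussian")
  pred <- unname(stats::predict(fit, data.frame(distance_cm = grid_cm)))
  # grid points beyond the observed distance range: carry the nearest fit
  if (anyNA(pred)) {
    okp <- which(!is.na(pred))
    if (!length(okp)) return(rep(NA_real_, length(grid_cm)))
    pred[seq_len(min(okp) - 1)] <- pred[min(okp)]
    if (max(okp) < length(pred))
      pred[(max(okp) + 1):length(pred)] <- pred[max(okp)]
  }
  pmin(pmax(pred, 0), 1)
}

#' Replicated LD-decay grid for one chromosome
#'
#' Repeats pair sampling plus curve fitting `n_reps` times (replicate `r`
#' uses seed `seed + r`) and returns the per-grid-point mean and sample
#' variance over replicates, along with the replicate curves.
#'
#' @param g a [geno()] object.
#' @param chromosome chromosome label.
#' @param dense_map a `"genetic_map"`.
#' @param grid_cm evaluation grid.
#' @param n_pairs pairs per replicate.
#' @param n_reps replicates.
#' @param seed base seed.
#' @param span,degree,min_pairs passed to [fit_decay()].
#' @return List: `mean`, `var` (vectors over the grid; `var` is `NA` for
#'   a single replicate), `replicates` (matrix reps x grid), `n_reps`.
#' @export
replicate_grid <- function(g, chromosome, dense_map, grid_cm,
                           n_pairs = 20000, n_reps = 30, seed = 1L,
                           span = 0.05, degree = 2, min_pairs = 50) {
  curves <- matrix(NA_real_, n_reps, length(grid_cm))
  for (r in seq_len(n_reps)) {
    pr <- sample_pairs(g, chromosome, dense_map, n_pairs, seed = seed + r)
    curves[r, ] <- fit_decay(pr$distance_cm, pr$r2, grid_cm, span = span,
                             degree = degree, min_pairs = min_pairs)
  }
  ok <- stats::complete.cases(curves)
  if (!any(ok)) return(NULL)
  curves <- curves[ok, , drop = FALSE]
  list(mean = colMeans(curves),
       var = if (nrow(curves) >= 2) apply(curves, 2, stats::var) else
         rep(NA_real_, length(grid_cm)),
       replicates = curves, n_reps = nrow(curves))
}

#' Inverse-variance combination across chromosomes
#'
#' Weighted mean with weights `1/var`; weighted standard error
#' `sqrt(1 / sum(w))`; 95% interval `mean +/- 1.96 se`. A chromosome with
#' zero variance at a grid point has its weight capped at the largest
#' finite weight among the other chromosomes at that point (so the mean
#' stays defined); if every variance is zero the plain mean is returned
#' with zero standard error.
#'
#' @param means,vars matrices (chromosomes x grid points) or vectors.
#' @return List: `mean`, `se`, `lo`, `hi` (vectors over grid points).
#' @export
combine_chromosomes <- function(means, vars) {
  if (is.null(dim(means))) {  # vectors: per-chromosome values, one point
    means <- cbind(means); vars <- cbind(vars)
  }
  ng <- ncol(means)
  out_m <- out_se <- rep(NA_real_, ng)
  for (k in seq_len(ng)) {
    m <- means[, k]; v <- vars[, k]
    ok <- !is.na(m) & !is.na(v)
    m <- m[ok]; v <- v[ok]
    if (!length(m)) next
    w <- 1 / v
    if (any(!is.finite(w))) {
      cap <- if (any(is.finite(w))) max(w[is.finite(w)]) else 1
      w[!is.finite(w)] <- cap
    }
    out_m[k] <- sum(w * m) / sum(w)
    out_se[k] <- sqrt(1 / sum(w))
    if (all(v == 0)) out_se[k] <- 0
  }
  list(mean = out_m, se = out_se,
       lo = out_m - 1.96 * out_se, hi = out_m + 1.96 * out_se)
}

#' Fit LD decay across the genome
#'
#' The main LD fit: for every chromosome of the genotype object, samples
#' `n_pairs` marker pairs `n_reps` times, fits a local-polynomial decay
#' curve per replicate on a fixed genetic-distance grid, and combines
#' chromosomes by inverse-variance weighting of the replicate means.
#' Chromosome `c` and replicate `r` draw pairs with seed
#' `seed + 7919 (c - 1) + r` so replicates are reproducible and
#' chromosomes decoupled.
#'
#' @param g a [geno()] object (typically after QC and the LD-stage MAF
#'   filter, autosomes only).
#' @param dense_map a `"genetic_map"` from [m1_positions()],
#'   [m2_positions()] or [m3_positions()].
#' @param grid_min,grid_max,grid_points grid of genetic distances in cM
#'   (defaults 0.5-50 cM at 2000 points).
#' @param n_pairs,n_reps sampling effort per chromosome.
#' @param seed integer seed.
#' @param span,degree loess settings for the decay smoother.
#' @param min_pairs minimum usable pairs per replicate.
#' @return An object of class `"ld_decay"`: grid, per-chromosome means,
#'   variances and replicate curves, and the combined decay curve with
#'   95% interval.
#' @export
ld_decay <- function(g, dense_map, grid_min = 0.5, grid_max = 50,
                     grid_points = 2000, n_pairs = 20000, n_reps = 30,
                     seed = 1L, span = 0.05, degree = 2, min_pairs = 50) {
  stopifnot(inherits(g, "geno"))
  grid_cm <- seq(grid_min, grid_max, length.out = grid_points)
  chrs <- unique(g$snps$chromosome)
  res <- list()
  for (ci in seq_along(chrs)) {
    rg <- replicate_grid(g, chrs[ci], dense_map, grid_cm,
                         n_pairs = n_pairs, n_reps = n_reps,
                         seed = seed + 7919L * (ci - 1L),
                         span = span, degree = degree,
                         min_pairs = min_pairs)
    if (is.null(rg)) {
      warning("chromosome ", chrs[ci], ": no usable replicate; excluded")
      next
    }
    res[[chrs[ci]]] <- rg
  }
  if (!length(res)) stop("no chromosome produced a decay curve")
  means <- do.call(rbind, lapply(res, `[[`, "mean"))
  vars <- do.call(rbind, lapply(res, `[[`, "var"))
  comb <- combine_chromosomes(means, vars)
  structure(list(grid_cm = grid_cm, method = attr(dense_map, "method"),
                 chromosomes = names(res), mean = means, var = vars,
                 replicates = lapply(res, `[[`, "replicates"),
                 combined = data.frame(grid_cm = grid_cm,
                                       r2 = comb$mean, se = comb$se,
                                       ci95_low = comb$lo,
                                       ci95_high = comb$hi),
                 n_pairs = n_pairs, n_reps = n_reps, seed = seed),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay fit (", x$method, "): ", length(x$chromosomes),
      " chromosomes, grid ", min(x$grid_cm), "-", max(x$grid_cm), " cM (",
      length(x$grid_cm), " points), ", x$n_reps, " x ", x$n_pairs,
      " pairs\n", sep = "")
  i <- c(1, round(length(x$grid_cm) / 2), length(x$grid_cm))
  with(x$combined[i, ], cat(sprintf(
    "  r2 at %.1f cM: %.4f [%.4f, %.4f]\n", grid_cm, r2, ci95_low,
    ci95_high)))
  invisible(x)
}

#' @export
summary.ld_decay <- function(object, at_cm = c(1, 5, 10, 25, 50), ...) {
  idx <- vapply(at_cm, function(d) which.min(abs(object$grid_cm - d)),
                integer(1))
  out <- object$combined[idx, ]
  rownames(out) <- NULL
  out
}

#' @export
as.data.frame.ld_decay <- function(x, ...) {
  df <- x$combined
  per <- t(x$mean)
  colnames(per) <- paste0("r2_", x$chromosomes)
  cbind(df, per)
}

#' @export
plot.ld_decay <- function(x, ...) {
  with(x$combined, {
    graphics::plot(grid_cm, r2, type = "l", xlab = "distance (cM)",
                   ylab = expression(E(r^2)),
                   main = paste("LD decay,", x$method), ...)
    graphics::lines(grid_cm, ci95_low, lty = 3)
    graphics::lines(grid_cm, ci95_high, lty = 3)
  })
  invisible(x)
}

#' Serialize an LD grid / decay curve
#'
#' One TSV per map method: grid distance, per-chromosome mean and
#' variance columns, then the weighted summary columns.
#'
#' @param x an `"ld_decay"` object.
#' @param path output path.
#' @export
write_ld_grid <- function(x, path) {
  df <- data.frame(grid_cm = x$grid_cm)
  for (i in seq_along(x$chromosomes)) {
    df[[paste0("mean_", x$chromosomes[i])]] <- x$mean[i, ]
    df[[paste0("var_", x$chromosomes[i])]] <- x$var[i, ]
  }
  df$weighted_r2 <- x$combined$r2
  df$weighted_se <- x$combined$se
  df$ci95_low <- x$combined$ci95_low
  df$ci95_high <- x$combined$ci95_high
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
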