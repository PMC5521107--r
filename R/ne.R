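#' Sved's LD-based effective population size
#'
#' Inverts Sved's drift expectation `E(r2) = 1 / (1 + 4 N c)`:
#' `Ne = 1/(4c) (1/E(r2) - 1)` with `c` the genetic distance in Morgans.
#' The optional sample-size correction subtracts `1/n` from the expected
#' r-squared before inversion (off by default, since chip-scale sample
#' sizes make it a small adjustment).
#'
#' @param e_r2 expected r-squared in `(0, 1]` (vectorized).
#' @param c_morgans genetic distance in Morgans, > 0.
#' @param n optional diploid sample size for the correction.
#' @return Ne estimates; `NA` where the (corrected) expectation is
#'   non-positive.
#' @export
sved_ne <- function(e_r2, c_morgans, n = NULL) {
  stopifnot(all(c_morgans > 0))
  if (!is.null(n)) e_r2 <- e_r2 - 1 / n
  out <- 1 / (4 * c_morgans) * (1 / e_r2 - 1)
  out[!is.na(e_r2) & e_r2 <= 0] <- NA_real_
  out
}

#' Generations in the past probed by a genetic distance
#'
#' `T = 1/(2c)`: LD between markers `c` Morgans apart reflects the
#' effective size about `T` generations ago; 50 cM probes one generation
#' back, 0.5 cM one hundred.
#'
#' @param c_morgans genetic distance in Morgans, > 0.
#' @return Generations in the past.
#' @export
generations <- function(c_morgans) {
  stopifnot(all(c_morgans > 0))
  1 / (2 * c_morgans)
}

#' Historical Ne trajectory from an LD-decay fit
#'
#' Transforms an [ld_decay()] fit point-wise through [sved_ne()]: each
#' grid distance (converted to Morgans) yields a generation `T = 1/(2c)`
#' and, per chromosome, an Ne estimate from that chromosome's mean decay
#' curve. Per-chromosome Ne variances are obtained by pushing each
#' replicate-level decay curve through the same transform and taking the
#' variance over replicates, mirroring how the LD variances were formed.
#' The combined trajectory is the inverse-variance weighted mean across
#' chromosomes with a 95% interval.
#'
#' @param ld an `"ld_decay"` object.
#' @param n optional diploid sample size for the Weir-Hill style `1/n`
#'   correction of the expected r-squared (default: no correction).
#' @return An object of class `"ne_history"`: `t_generations`,
#'   `c_morgans`, per-chromosome `ne` matrix and `var`, and `combined`
#'   (data frame with `ne`, `se`, `ci95_low`, `ci95_high`).
#' @export
ne_history <- function(ld, n = NULL) {
  stopifnot(inherits(ld, "ld_decay"))
  c_m <- ld$grid_cm / 100
  t_gen <- generations(c_m)
  ne_mean <- t(apply(ld$mean, 1, sved_ne, c_morgans = c_m, n = n))
  ne_var <- matrix(NA_real_, nrow(ld$mean), ncol(ld$mean),
                   dimnames = dimnames(ld$mean))
  for (i in seq_along(ld$chromosomes)) {
    reps <- ld$replicates[[ld$chromosomes[i]]]
    ne_reps <- t(apply(reps, 1, sved_ne, c_morgans = c_m, n = n))
    ne_var[i, ] <- apply(ne_reps, 2, stats::var)
  }
  comb <- combine_chromosomes(ne_mean, ne_var)
  structure(list(t_generations = t_gen, c_morgans = c_m,
                 grid_cm = ld$grid_cm, method = ld$method,
                 chromosomes = ld$chromosomes,
                 ne = ne_mean, var = ne_var,
                 combined = data.frame(t_generations = t_gen,
                                       c_morgans = c_m, ne = comb$mean,
                                       se = comb$se, ci95_low = comb$lo,
                                       ci95_high = comb$hi)),
            class = "ne_history")
}

#' @export
print.ne_history <- function(x, ...) {
  cat("Ne history (", x$method, "): ", length(x$chromosomes),
      " chromosomes, T = ", sprintf("%.0f", min(x$t_generations)), "-",
      sprintf("%.0f", max(x$t_generations)), " generations\n", sep = "")
  print(extract_at_generations(x, c(1, 5, 20, 50, 100)))
  invisible(x)
}

#' @export
summary.ne_history <- function(object, ...) {
  extract_at_generations(object, c(1, 5, 20, 50, 100))
}

#' @export
as.data.frame.ne_history <- function(x, ...) {
  df <- x$combined
  per <- t(x$ne)
  colnames(per) <- paste0("ne_", x$chromosomes)
  cbind(df, per)
}

#' @export
plot.ne_history <- function(x, log = "y", ...) {
  with(x$combined, {
    ok <- !is.na(ne) & ne > 0
    graphics::plot(t_generations[ok], ne[ok], type = "l", log = log,
                   xlab = "generations ago", ylab = expression(N[e]),
                   main = paste("Ne history,", x$method), ...)
    graphics::lines(t_generations[ok], pmax(ci95_low[ok], 1e-6), lty = 3)
    graphics::lines(t_generations[ok], ci95_high[ok], lty = 3)
  })
  invisible(x)
}

#' Ne at selected generations
#'
#' Linear interpolation of the combined trajectory on the generation
#' axis, plus the difference between the oldest and most recent targets
#' (the conventional Ne(100) - Ne(1) column).
#'
#' @param curve an `"ne_history"` object.
#' @param targets generations at which to report.
#' @return One-row data frame: one column per target plus the
#'   difference.
#' @export
extract_at_generations <- function(curve, targets = c(1, 5, 20, 50, 100)) {
  t <- curve$t_generations
  ne <- curve$combined$ne
  if (any(targets < min(t) - 1e-9 | targets > max(t) + 1e-9))
    stop("target generation outside the grid range [",
         sprintf("%.2f", min(t)), ", ", sprintf("%.2f", max(t)), "]")
  ord <- order(t)
  vals <- stats::approx(t[ord], ne[ord], xout = targets, rule = 2)$y
  out <- as.data.frame(as.list(round(vals, 1)))
  names(out) <- paste0("ne_", targets)
  out$diff_last_first <- round(vals[length(vals)] - vals[1], 1)
  out
}

#' Normality screen of per-chromosome estimates
#'
#' Shapiro-Wilk test of the across-chromosome distribution at each grid
#' point, flagged at the Bonferroni-corrected level `alpha / n_grid`.
#'
#' @param values matrix of per-chromosome estimates (chromosomes x grid
#'   points), e.g. the `ne` or `mean` slot of a fit.
#' @param alpha family-wise level (default 0.05).
#' @return Data frame: `grid_index`, `statistic`, `p_value`, `flagged`;
#'   attribute `"threshold"` holds the per-test level.
#' @export
normality_screen <- function(values, alpha = 0.05) {
  values <- rbind(values)
  stopifnot(nrow(values) >= 3)
  ng <- ncol(values)
  thr <- alpha / ng
  res <- apply(values, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 3 || stats::sd(v) == 0)
      return(c(NA_real_, NA_real_))
    sw <- stats::shapiro.test(v)
    c(unname(sw$statistic), sw$p.value)
  })
  out <- data.frame(grid_index = seq_len(ng), statistic = res[1, ],
                    p_value = res[2, ],
                    flagged = !is.na(res[2, ]) & res[2, ] <= thr)
  attr(out, "threshold") <- thr
  out
}

#' Parametric-bootstrap comparison of two methods at a grid point
#'
#' Compares the per-chromosome estimates produced by two map methods at
#' one grid point. Observed statistics: `T_mean = |mean1 - mean2|`
#' (inverse-variance weighted means when weights are supplied) and
#' `T_var = |log(var1 / var2)|`. Null samples are drawn parametrically:
#' for the mean test both sets are resampled from normals with the
#' pooled mean (each keeping its own variance); for the variance test
#' from normals with the pooled variance (each keeping its own mean).
#' `p = (1 + #(T_boot >= T_obs)) / (n_boot + 1)`.
#'
#' @param values_m1,values_m2 per-chromosome estimates (equal length,
#'   at least 3).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param weights_m1,weights_m2 optional inverse-variance weights.
#' @param alpha rejection level.
#' @return List of class `"boot_compare"`: `t_mean`, `t_var`, `p_mean`,
#'   `p_var`, `rejected_mean`, `rejected_var`.
#' @export
bootstrap_compare <- function(values_m1, values_m2, n_boot = 1000,
                              seed = 1L, weights_m1 = NULL,
                              weights_m2 = NULL, alpha = 0.05) {
  ok <- !is.na(values_m1) & !is.na(values_m2)
  x <- values_m1[ok]; y <- values_m2[ok]
  if (length(x) < 3) stop("need at least 3 chromosomes")
  wmean <- function(v, w) if (is.null(w)) mean(v) else
    sum(w[ok] * v) / sum(w[ok])
  m1 <- wmean(x, weights_m1); m2 <- wmean(y, weights_m2)
  v1 <- stats::var(x); v2 <- stats::var(y)
  t_mean <- abs(m1 - m2)
  t_var <- abs(log(v1 / v2))
  nx <- length(x); ny <- length(y)
  pool_m <- (m1 + m2) / 2
  pool_v <- (v1 + v2) / 2
  local_seed(seed, {
    # mean test: common mean, own variances
    bx <- matrix(stats::rnorm(n_boot * nx, pool_m, sqrt(v1)), n_boot)
    by <- matrix(stats::rnorm(n_boot * ny, pool_m, sqrt(v2)), n_boot)
    tb_mean <- abs(rowMeans(bx) - rowMeans(by))
    # variance test: common variance, own means
    bx2 <- matrix(stats::rnorm(n_boot * nx, m1, sqrt(pool_v)), n_boot)
    by2 <- matrix(stats::rnorm(n_boot * ny, m2, sqrt(pool_v)), n_boot)
    rv <- function(m) apply(m, 1, stats::var)
    tb_var <- abs(log(rv(bx2) / rv(by2)))
    p_mean <- (1 + sum(tb_mean >= t_mean)) / (n_boot + 1)
    p_var <- (1 + sum(tb_var >= t_var)) / (n_boot + 1)
    structure(list(t_mean = t_mean, t_var = t_var, p_mean = p_mean,
                   p_var = p_var, rejected_mean = p_mean <= alpha,
                   rejected_var = p_var <= alpha, alpha = alpha,
                   n_boot = n_boot),
              class = "boot_compare")
  })
}

#' @export
print.boot_compare <- function(x, ...) {
  cat(sprintf(
    "parametric bootstrap (B = %d): mean p = %.4f%s, var p = %.4f%s\n",
    x$n_boot, x$p_mean, if (x$rejected_mean) " *" else "",
    x$p_var, if (x$rejected_var) " *" else ""))
  invisible(x)
}

#' Compare two fits across the grid
#'
#' Runs [bootstrap_compare()] at a subset of grid points on the
#' per-chromosome estimates of two [ld_decay()] or [ne_history()] fits
#' of the same data under different map methods.
#'
#' @param fit1,fit2 two fits of the same class.
#' @param at grid indices to test (default 20 equally spaced points).
#' @param n_boot,seed,alpha passed to [bootstrap_compare()].
#' @return Data frame: `grid_cm`, `p_mean`, `p_var`, `rejected_mean`,
#'   `rejected_var`.
#' @export
compare_methods <- function(fit1, fit2, at = NULL, n_boot = 1000,
                            seed = 1L, alpha = 0.05) {
  stopifnot(class(fit1) == class(fit2))
  vals <- function(f) if (inherits(f, "ne_history")) f$ne else f$mean
  v1 <- vals(fit1); v2 <- vals(fit2)
  ng <- ncol(v1)
  if (is.null(at)) at <- unique(round(seq(1, ng, length.out = 20)))
  rows <- lapply(seq_along(at), function(i) {
    k <- at[i]
    bc <- bootstrap_compare(v1[, k], v2[, k], n_boot = n_boot,
                            seed = seed + i, alpha = alpha)
    data.frame(grid_cm = fit1$grid_cm[k], p_mean = bc$p_mean,
               p_var = bc$p_var, rejected_mean = bc$rejected_mean,
               rejected_var = bc$rejected_var)
  })
  do.call(rbind, rows)
}

#' Write an Ne trajectory as TSV
#'
#' Columns: generations, Morgans, per-chromosome Ne, combined Ne and the
#' 95% interval.
#'
#' @param x an `"ne_history"` object.
#' @param path output path.
#' @export
write_ne_curve <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
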