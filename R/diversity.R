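#' Observed heterozygosity per animal and per group
#'
#' Per-animal He is the fraction of heterozygous calls among non-missing
#' calls; group He is the mean over the group's animals. Computed before
#' any imputation (missing calls simply drop out of the denominator).
#'
#' @param g a [geno()] object.
#' @param groups optional group labels per animal.
#' @return List with `animal` (named vector) and, when `groups` is given,
#'   `group` (named vector of group means).
#' @export
heterozygosity <- function(g, groups = NULL) {
  stopifnot(inherits(g, "geno"))
  nhet <- rowSums(g$dosage == 1, na.rm = TRUE)
  nobs <- rowSums(!is.na(g$dosage))
  he <- nhet / nobs
  if (any(nobs == 0)) {
    warning(sum(nobs == 0), " animal(s) with zero non-missing calls ",
            "excluded from He")
    he[nobs == 0] <- NA
  }
  names(he) <- g$animals$animal_id
  out <- list(animal = he)
  if (!is.null(groups))
    out$group <- tapply(he, groups, mean, na.rm = TRUE)
  out
}

#' Genomic relationship matrix
#'
#' VanRaden-style GRM: `G = Z Z' / sum(2 p_m (1 - p_m))` with `Z` the
#' dosage matrix centered at `2 p_m`. Missing dosages contribute zero
#' after centering (equivalent to per-SNP mean imputation). Monomorphic
#' SNPs contribute nothing and are dropped from the denominator.
#'
#' Frequency models: `"pooled"` uses the overall allele frequency per SNP;
#' `"group"` centers each animal at its group's frequency; and
#' `"breed_regression"` fits, per SNP, a least-squares regression of
#' dosage on the breed-composition columns (plus the implied "other"
#' remainder) and centers each animal at its fitted expected dosage,
#' which accounts for breed composition in admixed animals.
#'
#' @param g a [geno()] object.
#' @param freq_model one of `"pooled"`, `"group"`, `"breed_regression"`.
#' @param groups group labels (required for `"group"`).
#' @return A list of class `"grm"`: `animal_ids`, `g` (symmetric matrix).
#' @export
compute_grm <- function(g, freq_model = c("pooled", "group",
                                          "breed_regression"),
                        groups = NULL) {
  stopifnot(inherits(g, "geno"))
  freq_model <- match.arg(freq_model)
  d <- g$dosage
  n <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n)
  poly <- which(!is.na(p) & p > 0 & p < 1)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  denom <- sum(2 * p * (1 - p))

  if (freq_model == "pooled") {
    z <- sweep(d, 2, 2 * p)
  } else if (freq_model == "group") {
    if (is.null(groups)) stop("freq_model = 'group' needs groups")
    z <- matrix(NA_real_, nrow(d), ncol(d))
    for (grp in unique(groups)) {
      rows <- which(groups == grp)
      dg <- d[rows, , drop = FALSE]
      pg <- colSums(dg, na.rm = TRUE) / (2 * pmax(colSums(!is.na(dg)), 1))
      z[rows, ] <- sweep(dg, 2, 2 * pg)
    }
  } else {
    if (is.null(g$breed_comp))
      stop("freq_model = 'breed_regression' needs breed_comp on the object")
    x <- g$breed_comp
    x <- cbind(x, other = pmax(0, 1 - rowSums(x)))
    # fitted expected dosage per animal per SNP; one multi-response lsfit
    fit <- stats::lm.fit(x, ifelse(is.na(d), 0, d))
    expd <- x %*% fit$coefficients
    z <- d - expd
  }
  z[is.na(z)] <- 0
  gmat <- tcrossprod(z) / denom
  gmat <- (gmat + t(gmat)) / 2
  structure(list(animal_ids = g$animals$animal_id, g = gmat),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("GRM over", length(x$animal_ids), "animals; mean diagonal",
      sprintf("%.4f", mean(diag(x$g))), "\n")
  invisible(x)
}

#' Average genomic inbreeding
#'
#' Mean of the GRM diagonal minus 1, over the given group (all animals by
#' default).
#'
#' @param grm a [compute_grm()] result.
#' @param group optional index/logical/character selection of animals.
#' @return A single inbreeding coefficient.
#' @export
inbreeding <- function(grm, group = NULL) {
  idx <- if (is.null(group)) seq_along(grm$animal_ids) else group
  if (is.character(idx)) idx <- match(idx, grm$animal_ids)
  if (!length(idx)) stop("empty group")
  mean(diag(grm$g)[idx]) - 1
}

#' Mean relationship within and between groups
#'
#' Within-group means exclude the diagonal; between-group means average
#' over all cross pairs.
#'
#' @param grm a [compute_grm()] result.
#' @param groups group labels per animal.
#' @return A symmetric group-by-group matrix.
#' @export
kinship_summary <- function(grm, groups) {
  labs <- sort(unique(as.character(groups)))
  out <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq(i, length(labs))) {
    ri <- which(groups == labs[i]); rj <- which(groups == labs[j])
    block <- grm$g[ri, rj, drop = FALSE]
    if (i == j) {
      if (length(ri) < 2) { out[i, j] <- NA_real_; next }
      out[i, j] <- (sum(block) - sum(diag(block))) /
        (length(ri) * (length(ri) - 1))
    } else {
      out[i, j] <- out[j, i] <- mean(block)
    }
  }
  out
}

#' Genetic distance matrix from a GRM
#'
#' `d_ij = 1 - g_ij` off the diagonal, `d_ii = 0`.
#'
#' @param grm a [compute_grm()] result.
#' @return A list of class `"gdist"`: `animal_ids`, `d`.
#' @export
distance_matrix <- function(grm) {
  d <- 1 - grm$g
  diag(d) <- 0
  structure(list(animal_ids = grm$animal_ids, d = d), class = "gdist")
}

#' Classical (metric) multidimensional scaling
#'
#' Torgerson scaling of the distance matrix: double-centering of squared
#' distances, eigendecomposition, coordinates scaled by root eigenvalues.
#' Negative eigenvalues are truncated to zero with a warning; if fewer
#' than `k` positive eigenvalues exist, fewer columns are returned.
#'
#' @param d a [distance_matrix()] result or a square distance matrix.
#' @param k number of dimensions (default 2).
#' @return List of class `"mds"`: `animal_ids`, `coordinates`,
#'   `eigenvalues`.
#' @export
classical_mds <- function(d, k = 2) {
  ids <- if (inherits(d, "gdist")) d$animal_ids else rownames(d)
  m <- if (inherits(d, "gdist")) d$d else as.matrix(d)
  stopifnot(k >= 1, k <= nrow(m) - 1)
  fit <- stats::cmdscale(m, k = k, eig = TRUE)
  eig <- fit$eig
  if (any(eig < -1e-8 * max(abs(eig))))
    warning("negative eigenvalues truncated to zero ",
            "(distances not fully Euclidean)")
  got <- ncol(fit$points)
  if (got < k)
    warning("only ", got, " positive dimensions available; returning ", got)
  structure(list(animal_ids = ids, coordinates = fit$points,
                 eigenvalues = pmax(eig[seq_len(got)], 0)),
            class = "mds")
}

#' Flag the most genetically distant animals within each group
#'
#' Scores each animal by its sum of squared distances to all other
#' animals of the same group and flags the `ceiling(fraction * size)`
#' highest-scoring animals per group (none for groups of size 1 or when
#' `fraction = 0`). Ties are broken by animal id for determinism.
#'
#' @param d a [distance_matrix()] result.
#' @param groups group labels per animal.
#' @param fraction proportion to flag (default 0.01).
#' @return Character vector of flagged animal ids.
#' @export
flag_outliers <- function(d, groups, fraction = 0.01) {
  stopifnot(inherits(d, "gdist"), fraction >= 0, fraction < 1)
  if (fraction == 0) return(character())
  flagged <- character()
  for (grp in unique(groups)) {
    rows <- which(groups == grp)
    if (length(rows) < 2) next
    block <- d$d[rows, rows, drop = FALSE]
    score <- rowSums(block^2)
    ids <- d$animal_ids[rows]
    nflag <- ceiling(fraction * length(rows))
    ord <- order(-score, ids)
    flagged <- c(flagged, ids[ord[seq_len(nflag)]])
  }
  flagged
}

#' Write diversity outputs
#'
#' TSV serializations: the GRM and distance matrix with an id header row
#' and column, MDS coordinates as (animal_id, dim1..dimk), and a
#' diversity summary table (He, inbreeding, kinship) per group.
#'
#' @param x object to write.
#' @param path output path.
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "grm")) x$g else if (inherits(x, "gdist")) x$d else
    as.matrix(x)
  ids <- if (inherits(x, c("grm", "gdist"))) x$animal_ids else rownames(m)
  df <- data.frame(id = ids, m, check.names = FALSE)
  colnames(df) <- c("id", ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @export
write_mds_tsv <- function(x, path) {
  stopifnot(inherits(x, "mds"))
  df <- data.frame(animal_id = x$animal_ids, x$coordinates)
  colnames(df) <- c("animal_id", paste0("dim", seq_len(ncol(x$coordinates))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Per-group diversity summary
#'
#' @param g a [geno()] object.
#' @param grm a [compute_grm()] result on the same animals.
#' @param groups group labels per animal.
#' @return Data frame with per-group He and inbreeding plus the kinship
#'   matrix as an attribute `"kinship"`.
#' @export
diversity_summary <- function(g, grm, groups) {
  he <- heterozygosity(g, groups)$group
  labs <- names(he)
  fv <- vapply(labs, function(l) inbreeding(grm, which(groups == l)),
               numeric(1))
  out <- data.frame(group = labs, heterozygosity = as.numeric(he),
                    inbreeding = fv, row.names = NULL)
  attr(out, "kinship") <- kinship_summary(grm, groups)
  out
}
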