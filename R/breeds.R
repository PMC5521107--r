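#' Assign breed-group labels from breed-composition proportions
#'
#' Rules, evaluated in order on the Romney (Rom), Coopworth (Coop),
#' Perendale (Peren) and Texel (Tex) proportions:
#' a pure group when any one of the four breeds reaches at least 0.75;
#' otherwise with RCP = Rom + Coop + Peren, `CompRCP` when RCP > 0.5 and
#' Tex < 0.25; `CompRCPT` when RCP > 0.5 and Tex >= 0.25; `Comprcp2` when
#' 0.3 < RCP <= 0.5; otherwise `unassigned`. Proportions of breeds other
#' than the four named ones are ignored (they make up the "Other"
#' remainder); proportions must be non-negative and sum to at most 1.
#'
#' @param comp a named numeric vector of proportions, or a matrix/data
#'   frame with one row per animal and breed labels as column names
#'   (case-sensitive: `Rom`, `Coop`, `Peren`, `Tex`; absent columns count
#'   as 0).
#' @return A character vector of group labels.
#' @export
assign_breed_group <- function(comp) {
  if (is.null(dim(comp))) comp <- t(as.matrix(comp))
  comp <- as.matrix(as.data.frame(comp))
  if (any(comp < 0, na.rm = TRUE))
    stop("breed proportions must be non-negative")
  tot <- rowSums(comp, na.rm = TRUE)
  if (any(tot > 1 + 1e-8))
    stop("breed proportions must sum to at most 1")
  getcol <- function(nm) if (nm %in% colnames(comp)) comp[, nm] else
    rep(0, nrow(comp))
  rom <- getcol("Rom"); coop <- getcol("Coop")
  peren <- getcol("Peren"); tex <- getcol("Tex")
  rcp <- rom + coop + peren
  out <- rep("unassigned", nrow(comp))
  out[rcp > 0.3 & rcp <= 0.5] <- "Comprcp2"
  out[rcp > 0.5 & tex >= 0.25] <- "CompRCPT"
  out[rcp > 0.5 & tex < 0.25] <- "CompRCP"
  out[tex >= 0.75] <- "Tex"
  out[peren >= 0.75] <- "Peren"
  out[coop >= 0.75] <- "Coop"
  out[rom >= 0.75] <- "Rom"
  out
}
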