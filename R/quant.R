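## FAME-based quantification of phospholipid products. Methylation
## stoichiometry: 1 mol PC releases 2 mol FAME (two acyl chains), 1 mol LPC
## releases 1 mol FAME, so band mole yields follow directly from total FAME.

FAME_PER_MOL <- c(PC = 2, LPC = 1)

#' Fatty-acid profile of a TLC band
#'
#' @param band a [fame_table()] (or subset) holding one band's rows.
#' @return data.frame `fatty_acid`, `percent` summing to 100.
#' @export
fa_profile <- function(band) {
  tot <- sum(band$amount)
  if (tot <= 0) ltk_stop("ltk_zero_total", "band has zero total FAME amount")
  out <- data.frame(fatty_acid = band$fatty_acid,
                    percent = band$amount / tot * 100,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Incorporation percentage of one fatty acid in a band
#'
#' The share of the target fatty acid (e.g. DHA) among all fatty acids of
#' the product band, in percent.
#'
#' @param band a [fame_table()] rows of one band.
#' @param fatty_acid target id (default `"DHA"`).
#' @return percentage (0 if the fatty acid is absent).
#' @export
incorporation <- function(band, fatty_acid = "DHA") {
  p <- fa_profile(band)
  sum(p$percent[p$fatty_acid == fatty_acid])
}

#' Mole yield of a PC or LPC band from its total FAME
#'
#' moles(PC) = total FAME / 2; moles(LPC) = total FAME / 1;
#' yield = moles / initial moles x 100.
#'
#' @param band a [fame_table()] rows of one band (possibly empty).
#' @param species `"PC"` or `"LPC"`.
#' @param initial_moles starting moles of the phospholipid (> 0).
#' @return yield in percent.
#' @export
mole_yield <- function(band, species, initial_moles) {
  if (!is.character(species) || !species %in% names(FAME_PER_MOL))
    ltk_stop("ltk_unknown_species", "species must be one of: %s",
             paste(names(FAME_PER_MOL), collapse = ", "))
  if (!is.numeric(initial_moles) || initial_moles <= 0)
    ltk_stop("ltk_bad_number", "initial moles must be > 0")
  total <- if (nrow(band)) sum(band$amount) else 0
  moles <- total / FAME_PER_MOL[[species]]
  moles / initial_moles * 100
}

#' Quantification report over all bands of a FAME table
#'
#' @param fame a [fame_table()].
#' @param initial_moles named numeric: initial moles per band id present in
#'   the table (bands without an entry get profiles only).
#' @param target fatty acid whose incorporation is reported (default "DHA").
#' @return list with `profiles` (data.frame band, fatty_acid, percent),
#'   `incorporation` (band, percent) and `yields` (band, yield_percent).
#' @export
quant_report <- function(fame, initial_moles = NULL, target = "DHA") {
  bands <- unique(fame$band)
  prof <- do.call(rbind, lapply(bands, function(b) {
    p <- fa_profile(fame[fame$band == b, , drop = FALSE])
    cbind(band = b, p)
  }))
  inc <- data.frame(
    band = bands,
    percent = vapply(bands, function(b)
      incorporation(fame[fame$band == b, , drop = FALSE], target),
      numeric(1)))
  yields <- NULL
  if (!is.null(initial_moles)) {
    yb <- intersect(bands, names(initial_moles))
    yb <- yb[yb %in% names(FAME_PER_MOL)]
    yields <- data.frame(
      band = yb,
      yield_percent = vapply(yb, function(b)
        mole_yield(fame[fame$band == b, , drop = FALSE], b,
                   initial_moles[[b]]), numeric(1)))
  }
  list(profiles = prof, incorporation = inc, yields = yields)
}
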