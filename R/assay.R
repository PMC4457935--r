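#' Convert a coupled-assay NADH absorbance slope to an ATP hydrolysis rate
#'
#' In the coupled spectrophotometric ATPase assay each ATP hydrolyzed
#' oxidizes one NADH, monitored as an absorbance decline at 380 nm. With the
#' NADH extinction coefficient at 380 nm of 1.21 / mM / cm and a 1.0 cm path,
#' rate (uM ATP / min) = |slope| / (extinction * path) * 1000.
#'
#' @param slope Absorbance change per minute at 380 nm (negative while NADH
#'   is consumed; the magnitude is used).
#' @param extinction_mM NADH extinction coefficient (per mM per cm),
#'   default 1.21.
#' @param path_cm Cuvette path length in cm, default 1.0.
#' @return Rate in uM ATP per minute.
#' @examples
#' nadh_slope_to_rate(-0.00121)  # 1 uM/min
#' @export
nadh_slope_to_rate <- function(slope, extinction_mM = 1.21, path_cm = 1.0) {
  if (extinction_mM <= 0 || path_cm <= 0) {
    stop("extinction coefficient and path length must be positive")
  }
  abs(slope) / (extinction_mM * path_cm) * 1000
}

#' Apparent kcat of ssDNA-dependent ATP hydrolysis
#'
#' The observed hydrolysis rate divided by the concentration of available
#' protomer binding sites: one site per `site_size_nt` nucleotides of ssDNA
#' (3 for a RecA protomer), or the protein concentration when protein is
#' limiting — sites = min(protein, ssDNA / site_size_nt).
#'
#' @param rate_uM_min Observed rate (uM ATP / min).
#' @param ssdna_uM ssDNA concentration in uM nucleotides.
#' @param protein_uM Protein concentration in uM.
#' @param site_size_nt Nucleotides occluded per protomer (default 3).
#' @return Apparent kcat in per-minute units.
#' @examples
#' apparent_kcat(47.83, ssdna_uM = 5, protein_uM = 3)  # ~28.7 min^-1
#' @export
apparent_kcat <- function(rate_uM_min, ssdna_uM, protein_uM, site_size_nt = 3) {
  if (ssdna_uM <= 0 || protein_uM <= 0 || site_size_nt <= 0) {
    stop("concentrations and site size must be positive")
  }
  sites <- min(protein_uM, ssdna_uM / site_size_nt)
  if (sites <= 0) stop("no available binding sites")
  rate_uM_min / sites
}

#' Rate as a percent of a maximal rate
#'
#' @param k_oligo Rate (e.g. apparent kcat on a short oligo).
#' @param k_max Reference maximal rate (e.g. on circular ssDNA); must be > 0.
#' @param digits Decimal places for the reported value (default 1,
#'   round-half-even as in [round()]).
#' @return Percent, rounded for reporting; use `digits = NA` for the raw value.
#' @examples
#' percent_of_max(15.7, 28.7)  # 54.7
#' @export
percent_of_max <- function(k_oligo, k_max, digits = 1) {
  if (k_max <= 0) stop("k_max must be > 0")
  p <- 100 * k_oligo / k_max
  if (is.na(digits)) p else round(p, digits)
}

#' Percent decline of a rate after a challenge
#'
#' @param before Rate before the challenge (> 0).
#' @param after Rate after.
#' @return 100 * (before - after) / before.
#' @examples
#' percent_decline(73.5, 58.2)  # ~20.8
#' @export
percent_decline <- function(before, after) {
  if (before <= 0) stop("before must be > 0")
  100 * (before - after) / before
}

#' Transconjugant yield per million donors
#'
#' @param colonies Recombinant colony count.
#' @param donors Donor cell count (> 0).
#' @return Colonies per 1e6 donors.
#' @export
transconjugant_frequency <- function(colonies, donors) {
  if (donors <= 0) stop("donors must be > 0")
  1e6 * colonies / donors
}

#' Fold change between two yields
#' @param a,b Yields; returns a / b.
#' @export
fold_change <- function(a, b) {
  if (b <= 0) stop("reference value must be > 0")
  a / b
}

#' Competition-plate mutant fractions with plate QC
#'
#' Colony-color competition scoring: per plate, the percent of colonies of
#' the mutant color. Plates outside 40-300 total colonies, or with fewer
#' than 20 colonies of either competitor, are flagged excluded and do not
#' enter per-cycle averages; cycles with no included plate get NA.
#'
#' @param plates data.frame with columns `cycle`, `red`, `white`
#'   (nonnegative counts), one row per plate.
#' @param mutant_color `"red"` or `"white"`.
#' @return List: `plates` (input plus `total`, `included`, `reason`,
#'   `percent_mutant`), `by_cycle` (data.frame `cycle`, `percent_mutant`
#'   averaged over included plates, NA when all excluded).
#' @examples
#' competition_fraction(data.frame(cycle = 1, red = 100, white = 100), "red")
#' @export
competition_fraction <- function(plates, mutant_color = c("red", "white")) {
  mutant_color <- match.arg(mutant_color)
  stopifnot(all(c("cycle", "red", "white") %in% names(plates)))
  if (any(plates$red < 0 | plates$white < 0)) stop("counts must be >= 0")
  plates$total <- plates$red + plates$white
  low_comp <- plates$red < 20 | plates$white < 20
  out_range <- plates$total < 40 | plates$total > 300
  plates$included <- !(low_comp | out_range)
  plates$reason <- ifelse(plates$included, "",
                          ifelse(out_range, "total outside 40-300",
                                 "competitor below 20"))
  mut <- plates[[mutant_color]]
  plates$percent_mutant <- ifelse(plates$total > 0, 100 * mut / plates$total, NA)
  by_cycle <- do.call(rbind, lapply(split(plates, plates$cycle), function(d) {
    inc <- d[d$included, , drop = FALSE]
    data.frame(cycle = d$cycle[1],
               percent_mutant = if (nrow(inc)) mean(inc$percent_mutant)
                                else NA_real_,
               n_included = nrow(inc), n_plates = nrow(d))
  }))
  rownames(by_cycle) <- NULL
  list(plates = plates, by_cycle = by_cycle)
}

#' UV survival percent
#'
#' @param treated_cfu,untreated_cfu Colony-forming units; untreated must
#'   be > 0.
#' @return 100 * treated / untreated.
#' @export
survival_percent <- function(treated_cfu, untreated_cfu) {
  if (untreated_cfu <= 0) stop("untreated_cfu must be > 0")
  100 * treated_cfu / untreated_cfu
}

#' Specific fluorescence
#'
#' Measured fluorescence divided by culture OD600; errors on a zero or
#' negative OD mirror the suppression of early low-density time points,
#' where the ratio of two near-zero readings is meaningless.
#'
#' @param fluorescence Measured fluorescence.
#' @param od600 Culture optical density (> 0).
#' @return Fluorescence / OD600.
#' @export
specific_fluorescence <- function(fluorescence, od600) {
  if (any(od600 <= 0)) stop("od600 must be > 0")
  fluorescence / od600
}
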