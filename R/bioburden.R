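# Plate-count arithmetic and spore-to-viable accounting against the Space
# Studies Board (SSB) specification of 50,000 viable cells per NSA spore.

#' Spore density from replicate pour plates
#'
#' Replicate plates are pooled: the concentrate titre is the total colony
#' count over the total volume plated, scaled to the whole concentrate and
#' normalized by the sampled surface area.  Pooling equals per-plate
#' averaging when plated volumes are equal and stays well-defined when
#' they are not.
#'
#' @param colonies integer colony counts, one per replicate plate
#' @param plated_ml volume plated per plate in mL (scalar recycled, or one
#'   value per plate)
#' @param concentrate_ml total concentrate volume in mL
#' @param area_m2 sampled surface area in square metres
#' @return spores (CFU) per square metre
#' @examples
#' cfu_per_area(c(1, 2, 0, 1), plated_ml = 0.1, concentrate_ml = 5,
#'              area_m2 = 1)  # 50 spores/m^2
#' @export
cfu_per_area <- function(colonies, plated_ml, concentrate_ml, area_m2) {
  if (length(plated_ml) == 1L) plated_ml <- rep(plated_ml, length(colonies))
  stopifnot(length(plated_ml) == length(colonies), length(colonies) >= 1L)
  if (any(colonies < 0) || any(abs(colonies - round(colonies)) > 1e-8))
    stop("colony counts must be non-negative integers")
  if (sum(plated_ml) <= 0) stop("total plated volume must be positive")
  if (concentrate_ml <= 0 || area_m2 <= 0)
    stop("concentrate volume and area must be positive")
  (sum(colonies) / sum(plated_ml)) * concentrate_ml / area_m2
}

#' SSB-predicted viable bioburden from a spore density
#'
#' @param spores_per_m2 NSA spore density
#' @param ssb_ratio viable cells per NSA spore (default 50,000, the Space
#'   Studies Board conversion factor)
#' @return predicted viable cells per square metre
#' @export
ssb_viable_estimate <- function(spores_per_m2, ssb_ratio = 50000) {
  stopifnot(ssb_ratio > 0, all(spores_per_m2 >= 0))
  spores_per_m2 * ssb_ratio
}

#' Observed viable:spore ratio and comparison with the SSB specification
#'
#' @param viable_measured measured viable density (cells per square
#'   metre; e.g. from FACS or PMA-qPCR)
#' @param spores_per_m2 NSA spore density for the same sample
#' @param ssb_ratio the SSB conversion factor (default 50,000)
#' @return list: `ratio` (viable per spore; `NA` with `defined = FALSE`
#'   when the spore density is 0), `fraction_of_ssb` (ratio / SSB
#'   constant), `defined`
#' @export
observed_ratio <- function(viable_measured, spores_per_m2,
                           ssb_ratio = 50000) {
  stopifnot(viable_measured >= 0, spores_per_m2 >= 0, ssb_ratio > 0)
  if (spores_per_m2 == 0)
    return(list(ratio = NA_real_, fraction_of_ssb = NA_real_,
                defined = FALSE))
  ratio <- viable_measured / spores_per_m2
  list(ratio = ratio, fraction_of_ssb = ratio / ssb_ratio, defined = TRUE)
}

#' Total cultivable density from a spore fraction
#'
#' When spores make up a known fraction of the total heterotrophic
#' cultivable count, the total is the spore density divided by that
#' fraction.
#'
#' @param spores_per_m2 spore density
#' @param spore_fraction fraction of cultivable counts that are spores,
#'   in (0, 1]
#' @return total cultivable density per square metre
#' @examples
#' cultivable_from_fraction(36, 0.20)  # 180 cultivable/m^2
#' @export
cultivable_from_fraction <- function(spores_per_m2, spore_fraction) {
  if (!(spore_fraction > 0 && spore_fraction <= 1))
    stop("spore_fraction must be in (0, 1]")
  stopifnot(all(spores_per_m2 >= 0))
  spores_per_m2 / spore_fraction
}

#' Per-sample bioburden estimates from plate counts and viable measurements
#'
#' Convenience wrapper combining [cfu_per_area()], [ssb_viable_estimate()]
#' and [observed_ratio()] over a table of plate-count records.
#'
#' @param plate_records data frame with columns `sample_id`, `colonies`
#'   (comma-separated replicate counts or a list column), `plated_ml`,
#'   `concentrate_ml`, `area_m2`, and optionally `viable_measured`
#' @param ssb_ratio the SSB conversion factor
#' @return data frame with `spores_per_m2`, `ssb_viable`, and when a
#'   measured viable density is present, `observed_ratio` and
#'   `fraction_of_ssb`
#' @export
bioburden_table <- function(plate_records, ssb_ratio = 50000) {
  req <- c("sample_id", "colonies", "plated_ml", "concentrate_ml", "area_m2")
  stopifnot(all(req %in% names(plate_records)))
  parse_counts <- function(x) {
    if (is.list(x)) return(as.numeric(x[[1L]]))
    as.numeric(strsplit(as.character(x), ",", fixed = TRUE)[[1L]])
  }
  n <- nrow(plate_records)
  spores <- vapply(seq_len(n), function(i) cfu_per_area(
    parse_counts(plate_records$colonies[i]),
    plate_records$plated_ml[i],
    plate_records$concentrate_ml[i],
    plate_records$area_m2[i]), numeric(1L))
  out <- data.frame(sample_id = plate_records$sample_id,
                    spores_per_m2 = spores,
                    ssb_viable = ssb_viable_estimate(spores, ssb_ratio),
                    row.names = NULL)
  if ("viable_measured" %in% names(plate_records)) {
    obs <- lapply(seq_len(n), function(i) observed_ratio(
      plate_records$viable_measured[i], spores[i], ssb_ratio))
    out$viable_measured <- plate_records$viable_measured
    out$observed_ratio <- vapply(obs, `[[`, numeric(1L), "ratio")
    out$fraction_of_ssb <- vapply(obs, `[[`, numeric(1L), "fraction_of_ssb")
  }
  out
}
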