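#' Count reads overlapping a region by at least one base
#'
#' Intervals are 0-based half-open, so a read ending exactly where the region
#' starts does not overlap.
#'
#' @param placements `data.frame` with columns `read_id`, `seq_id`, `start`,
#'   `end`.
#' @param seq_id,start,end The region.
#' @return Integer count.
#' @export
region_read_count <- function(placements, seq_id, start, end) {
  sum(placements$seq_id == seq_id &
        placements$start < end & placements$end > start)
}

#' Normalized depth observation for a region
#'
#' RPM here is reads x 1e6 / (library size x region length); the absolute
#' scale is immaterial because only RPM ratios enter the copy-number
#' estimator (any common rescaling cancels).
#'
#' @param label Region label.
#' @param read_count Reads overlapping the region by at least 1 bp.
#' @param library_size Total reads in the library.
#' @param region_length Region length in bases.
#' @return A list with `label`, `read_count`, `library_size`, `rpm`.
#' @export
depth_observation <- function(label, read_count, library_size, region_length) {
  stopifnot(read_count >= 0, library_size >= read_count, region_length > 0)
  list(label = label, read_count = read_count, library_size = library_size,
       rpm = read_count * 1e6 / (library_size * region_length))
}

#' Copy number from depth: fold increase of gene over control average
#'
#' The estimate is the gene's normalized coverage divided by the mean of the
#' single-copy control coverages, reported to one decimal.
#'
#' @param gene_rpm Normalized coverage of the gene region.
#' @param control_rpms Normalized coverages of one or more single-copy
#'   control regions (all strictly positive).
#' @param digits Rounding digits for the reported estimate (default 1).
#' @return Estimated copy number (numeric).
#' @export
estimate_copies_depth <- function(gene_rpm, control_rpms, digits = 1L) {
  if (length(control_rpms) < 1L) stopf("at least one control required")
  if (any(control_rpms <= 0)) stopf("control coverage must be > 0")
  round(gene_rpm / mean(control_rpms), digits)
}

#' Standard-curve slope of a qPCR dilution series
#'
#' Ordinary least-squares slope of CT against log2(dilution), pooling
#' replicates. Perfect amplification doubles template requirement per
#' 2-fold dilution, giving slope 1.
#'
#' @param runs `data.frame` with columns `ct` and `dilution` (e.g. 1, 2, 4,
#'   8, 16, 32).
#' @return Slope in cycles per log2-dilution (signed OLS estimate).
#' @export
fit_dilution_slope <- function(runs) {
  stopifnot(all(c("ct", "dilution") %in% names(runs)))
  if (length(unique(runs$dilution)) < 2L)
    stopf("need at least 2 distinct dilutions to fit a slope")
  if (any(runs$ct <= 0)) stopf("CT values must be > 0")
  unname(stats::coef(stats::lm(ct ~ log2(dilution), data = runs))[[2L]])
}

#' Copy number from qPCR delta-CT with slope correction
#'
#' Each reaction's CT is corrected by multiplying by its primer set's
#' standard-curve slope; per plant the copy number is
#' `2 ^ (mean corrected reference CT - mean corrected target CT)`.
#'
#' @param ref_runs,target_runs `data.frame`s with columns `plant_id` and `ct`
#'   for the single-copy reference primer and the target primer; every plant
#'   must appear in both.
#' @param ref_slope,target_slope Standard-curve slopes for the two primer
#'   sets.
#' @return `data.frame` with columns `plant_id` and `copies`.
#' @export
estimate_copies_qpcr <- function(ref_runs, target_runs, ref_slope, target_slope) {
  stopifnot(is.finite(ref_slope), is.finite(target_slope))
  plants <- sort(unique(c(ref_runs$plant_id, target_runs$plant_id)))
  missing_ref <- setdiff(plants, ref_runs$plant_id)
  missing_tgt <- setdiff(plants, target_runs$plant_id)
  if (length(missing_ref) || length(missing_tgt))
    stopf("unmatched plant ids: %s",
          paste(c(missing_ref, missing_tgt), collapse = ", "))
  copies <- vapply(plants, function(p) {
    ref_ct <- mean(ref_runs$ct[ref_runs$plant_id == p] * ref_slope)
    tgt_ct <- mean(target_runs$ct[target_runs$plant_id == p] * target_slope)
    2 ^ (ref_ct - tgt_ct)
  }, numeric(1))
  data.frame(plant_id = plants, copies = unname(copies),
             stringsAsFactors = FALSE)
}

#' Aggregate per-plant, per-primer qPCR copy estimates for a genotype
#'
#' @param estimates Numeric vector of copy-number estimates from all primer
#'   combinations and plants of one genotype.
#' @return Arithmetic mean.
#' @export
aggregate_qpcr <- function(estimates) {
  if (length(estimates) == 0L) stopf("no estimates to aggregate")
  mean(estimates)
}
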