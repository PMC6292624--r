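#' Calling thresholds for array-intensity genotyping
#'
#' Records with normalized intensity r below `min_r` are rejected as
#' unreliable; the allele angle theta is then split into a REF cluster
#' (theta <= `theta_ref_max`), an ALT cluster (theta >= `theta_alt_min`) and
#' an AB band in between that is treated as missing (haploid mtDNA should not
#' cluster heterozygous). Samples whose overall call rate falls below
#' `min_sample_call_rate` are removed by [sample_qc()].
#'
#' @param min_r minimum reliable intensity (default 0.08).
#' @param theta_ref_max upper edge of the REF theta cluster (default 0.25).
#' @param theta_alt_min lower edge of the ALT theta cluster (default 0.75).
#' @param min_sample_call_rate minimum per-sample call rate (default 0.97).
#' @return An object of class `caller_thresholds`.
#' @export
caller_thresholds <- function(min_r = 0.08, theta_ref_max = 0.25,
                              theta_alt_min = 0.75,
                              min_sample_call_rate = 0.97) {
  stopifnot(min_r >= 0, theta_ref_max < theta_alt_min,
            min_sample_call_rate > 0 || min_sample_call_rate == 0,
            min_sample_call_rate <= 1)
  structure(list(min_r = min_r, theta_ref_max = theta_ref_max,
                 theta_alt_min = theta_alt_min,
                 min_sample_call_rate = min_sample_call_rate),
            class = "caller_thresholds")
}

#' Call haploid genotypes from intensity records
#'
#' Vectorized single-record rule: r < `min_r` gives MISSING; otherwise
#' theta <= `theta_ref_max` gives REF, theta >= `theta_alt_min` gives ALT, and
#' anything in the AB band between them is MISSING.
#'
#' @param r numeric vector of normalized intensities (>= 0).
#' @param theta numeric vector of allele angles in \[0, 1\].
#' @param t a [caller_thresholds].
#' @return Integer vector: 0 = REF, 1 = ALT, NA = MISSING.
#' @export
call_genotype <- function(r, theta, t = caller_thresholds()) {
  stopifnot(length(r) == length(theta))
  out <- rep(NA_integer_, length(r))
  reliable <- r >= t$min_r
  out[reliable & theta <= t$theta_ref_max] <- 0L
  out[reliable & theta >= t$theta_alt_min] <- 1L
  out
}

#' Call a genotype matrix from a table of intensity records
#'
#' Records cover a subset of (sample, locus) pairs; pairs without a record are
#' MISSING. Records at positions outside the declared panel are an input
#' error.
#'
#' @param records data.frame with columns `sample_id`, `position`, `r`,
#'   `theta` (e.g. from [simulate_intensities()]).
#' @param panel locus panel data.frame (`id`, `position`, `ref`, `alt`).
#' @param t a [caller_thresholds].
#' @param samples optional character vector fixing the sample set and order;
#'   defaults to order of first appearance in `records`.
#' @return A [genotype_matrix].
#' @export
call_matrix <- function(records, panel, t = caller_thresholds(),
                        samples = NULL) {
  if (is.null(samples)) samples <- unique(records$sample_id)
  calls <- matrix(NA_integer_, length(samples), nrow(panel),
                  dimnames = list(samples, panel$id))
  if (nrow(records)) {
    j <- match(records$position, panel$position)
    if (anyNA(j)) {
      stop("intensity record(s) at position(s) not in the panel: ",
           paste(unique(records$position[is.na(j)]), collapse = ", "))
    }
    i <- match(records$sample_id, samples)
    if (anyNA(i)) {
      stop("record(s) for sample(s) outside the declared sample set: ",
           paste(unique(records$sample_id[is.na(i)]), collapse = ", "))
    }
    calls[cbind(i, j)] <- call_genotype(records$r, records$theta, t)
  }
  genotype_matrix(calls, panel)
}

#' Sample-level call-rate QC
#'
#' Keeps a sample iff its fraction of non-missing calls over all panel loci is
#' at least `min_sample_call_rate`; removed samples are reported with their
#' call rates. Loci are never dropped, even when uninformative, so downstream
#' matrix dimensions are stable.
#'
#' @param g a [genotype_matrix].
#' @param t a [caller_thresholds].
#' @return list with `kept` (a [genotype_matrix]) and `removed` (data.frame
#'   `sample_id`, `call_rate` of the removed samples).
#' @export
sample_qc <- function(g, t = caller_thresholds()) {
  stopifnot(nrow(g$calls) >= 1L)
  rate <- rowMeans(!is.na(g$calls))
  keep <- rate >= t$min_sample_call_rate
  removed <- data.frame(sample_id = rownames(g$calls)[!keep],
                        call_rate = unname(rate[!keep]),
                        stringsAsFactors = FALSE)
  list(kept = genotype_matrix(g$calls[keep, , drop = FALSE], g$loci),
       removed = removed)
}

#' Write intensity records as tab-separated text
#'
#' @param records intensity data.frame (`sample_id`, `position`, `r`, `theta`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensities <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read intensity records written by [write_intensities()]
#'
#' @param path input path.
#' @return data.frame of intensity records.
#' @export
read_intensities <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
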