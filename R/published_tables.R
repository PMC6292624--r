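#' Published haplogroup counts from a nationwide Danish birth cohort
#'
#' Reference count tables transcribed from a published survey of mtDNA
#' haplogroups in 24,216 Danes born 1981-2005 (array-typed neonatal screening
#' samples). They serve as fixed inputs for reproducing the survey's printed
#' percentages and test statistics, and as calibration for the synthetic
#' cohort generator. The underlying registry data are not public; only these
#' aggregate counts are.
#'
#' @name published_counts
#' @return Each function returns a data.frame of counts (see Details).
#'
#' @details
#' * `published_macro_counts()`: macro-haplogroup counts (`macro_hg`, `n`)
#'   over the 24,216 haplotyped samples.
#' * `published_h_subhg_counts()`: sub-haplogroup bins of hg H (`sub_hg`,
#'   `n`) over the 10,783 sub-haplotyped H samples.
#' * `published_region_counts()`: haplogroup counts per administrative region
#'   (rows = haplogroup bins incl. `"NA"`, columns = regions).
#' * `published_period_counts()`: haplogroup counts for birth periods
#'   1981-1986 and 2000-2005 (rows = haplogroup bins incl. `"NA"`).
NULL

#' @rdname published_counts
#' @export
published_macro_counts <- function() {
  data.frame(
    macro_hg = c("L0", "L1", "L2", "L3", "L4", "L5", "L6", "M", "N", "R"),
    n = c(26L, 13L, 54L, 71L, 16L, 2L, 0L, 394L, 1700L, 21940L),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_counts
#' @export
published_h_subhg_counts <- function() {
  data.frame(
    sub_hg = c("H", "H1-H30b-H79a", "H2", "H3", "H4", "H5-36"),
    n = c(3924L, 4054L, 1058L, 699L, 220L, 828L),
    stringsAsFactors = FALSE
  )
}

#' @rdname published_counts
#' @export
published_region_counts <- function() {
  hg <- c("H", "I", "J", "K", "L", "M", "N", "R", "T", "U", "V", "W", "X", "NA")
  m <- cbind(
    Capital = c(2962L, 175L, 586L, 468L, 88L, 176L, 92L, 244L, 627L, 939L,
                229L, 96L, 134L, 2L),
    Zealand = c(1664L, 89L, 313L, 224L, 17L, 45L, 43L, 74L, 354L, 491L,
                116L, 57L, 60L, 3L),
    Central = c(2584L, 180L, 534L, 456L, 31L, 56L, 68L, 144L, 525L, 744L,
                195L, 74L, 67L, 2L),
    South = c(2259L, 148L, 464L, 364L, 20L, 79L, 61L, 119L, 434L, 666L,
              175L, 67L, 101L, 1L),
    North = c(1284L, 60L, 215L, 229L, 17L, 27L, 33L, 61L, 238L, 346L,
              73L, 24L, 24L, 1L)
  )
  out <- data.frame(hg = hg, m, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname published_counts
#' @export
published_period_counts <- function() {
  data.frame(
    hg = c("H", "I", "J", "K", "L", "M", "N", "R", "T", "U", "V", "W", "X",
           "NA"),
    period_1981_1986 = c(2162L, 130L, 405L, 359L, 8L, 44L, 50L, 102L, 447L,
                         579L, 163L, 56L, 64L, 1L),
    period_2000_2005 = c(2454L, 150L, 511L, 387L, 67L, 131L, 73L, 163L, 468L,
                         790L, 169L, 80L, 89L, 3L),
    stringsAsFactors = FALSE
  )
}
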