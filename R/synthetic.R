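#' Frequency models for synthetic cohorts
#'
#' A frequency model describes haplogroup proportions per region at the first
#' birth year, additive per-year trends, regional sampling weights and the
#' metropolitan fraction per region. Realized proportions for a given year are
#' `base + trend * (year - min(years))`, floored at zero and renormalized.
#'
#' @param regions character vector of region labels.
#' @param years inclusive integer birth-year range, e.g. `1981:2005`.
#' @param base_freq numeric matrix (regions x haplogroups) of proportions at
#'   `min(years)`; rows are renormalized to sum to 1.
#' @param trend named numeric vector of per-year additive changes in
#'   proportion (haplogroups absent from it have trend 0).
#' @param region_weights sampling weights per region (proportions of the
#'   cohort drawn from each region).
#' @param metro_frac named numeric vector: probability that a sample from the
#'   region is metropolitan.
#' @return An object of class `frequency_model`.
#' @export
frequency_model <- function(regions, years, base_freq, trend = numeric(),
                            region_weights = NULL, metro_frac = NULL) {
  regions <- as.character(regions)
  years <- as.integer(years)
  stopifnot(length(years) >= 1L, !anyNA(years))
  base_freq <- as.matrix(base_freq)
  if (is.null(rownames(base_freq))) rownames(base_freq) <- regions
  stopifnot(setequal(rownames(base_freq), regions))
  base_freq <- base_freq[regions, , drop = FALSE]
  if (any(base_freq < 0)) stop("base frequencies must be non-negative")
  if (any(rowSums(base_freq) <= 0)) stop("each region needs positive total frequency")
  base_freq <- base_freq / rowSums(base_freq)
  trend <- trend[names(trend) %in% colnames(base_freq) | seq_along(trend) > 0]
  unknown <- setdiff(names(trend), colnames(base_freq))
  if (length(unknown)) {
    stop("trend names a haplogroup not in base_freq: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(region_weights)) {
    region_weights <- stats::setNames(rep(1, length(regions)), regions)
  }
  region_weights <- region_weights[regions]
  region_weights <- region_weights / sum(region_weights)
  if (is.null(metro_frac)) metro_frac <- stats::setNames(rep(0.3, length(regions)), regions)
  metro_frac <- metro_frac[regions]
  structure(list(regions = regions, years = sort(years),
                 base_freq = base_freq, trend = trend,
                 region_weights = region_weights, metro_frac = metro_frac),
            class = "frequency_model")
}

#' Realized haplogroup proportions for one region and year
#'
#' @param model a [frequency_model].
#' @param region region label.
#' @param year birth year.
#' @return Named numeric vector of proportions (non-negative, summing to 1).
#' @export
realized_freq <- function(model, region, year) {
  f <- model$base_freq[region, ]
  dy <- year - min(model$years)
  if (length(model$trend)) {
    f[names(model$trend)] <- f[names(model$trend)] + model$trend * dy
  }
  f[f < 0] <- 0
  f / sum(f)
}

#' Validate that every model haplogroup exists in a tree
#'
#' @param model a [frequency_model].
#' @param tree a [haplo_tree].
#' @return `TRUE`, invisibly; otherwise an error naming the missing label.
#' @export
validate_model_tree <- function(model, tree) {
  missing_hg <- setdiff(colnames(model$base_freq), tree$nodes$name)
  if (length(missing_hg)) {
    stop("haplogroup label(s) not in the tree: ",
         paste(missing_hg, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a frequency model from a YAML configuration file
#'
#' The file mirrors the model fields: `regions`, `years` (two-element
#' min/max), `base_freq` (mapping region -> mapping haplogroup -> proportion),
#' `trend`, `region_weights`, `metro_frac`.
#'
#' @param path path to the YAML file.
#' @return A [frequency_model].
#' @export
frequency_model_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  hgs <- unique(unlist(lapply(cfg$base_freq, names)))
  bf <- t(vapply(cfg$regions, function(r) {
    v <- stats::setNames(rep(0, length(hgs)), hgs)
    v[names(cfg$base_freq[[r]])] <- unlist(cfg$base_freq[[r]])
    v
  }, numeric(length(hgs))))
  rownames(bf) <- cfg$regions
  frequency_model(
    regions = cfg$regions,
    years = cfg$years[[1]]:cfg$years[[2]],
    base_freq = bf,
    trend = if (length(cfg$trend)) unlist(cfg$trend) else numeric(),
    region_weights = if (length(cfg$region_weights)) unlist(cfg$region_weights) else NULL,
    metro_frac = if (length(cfg$metro_frac)) unlist(cfg$metro_frac) else NULL
  )
}

#' Default Danish-cohort frequency model
#'
#' Emulates the study conditions of a 1981-2005 nationwide birth cohort:
#' five administrative regions (Capital, Zealand, Central, South, North) with
#' regional sample weights proportional to published regional sample counts
#' (6,818 / 3,550 / 5,660 / 4,957 / 2,632), hg-level base frequencies per
#' region from the published regional distribution, and additive yearly
#' trends that raise macro-hg L from 0.2% to ~1.2%, M from 1.0% to ~2.4%, and
#' hg U from ~12.7% to ~14.3% over the 25 years (immigration-driven rises).
#' Trending haplogroups start at their 1981 national level scaled by the
#' region's relative level.
#'
#' @return A [frequency_model] whose haplogroup labels are nodes of
#'   [example_haplo_tree()] ("L3" stands in for the combined L macro-hgs).
#' @export
default_frequency_model <- function() {
  regions <- c("Capital", "Zealand", "Central", "South", "North")
  hgs <- c("H", "I", "J", "K", "L3", "M", "N", "R", "T", "U", "V", "W", "X")
  # regional percentages (rows Capital..North, cols as hgs above)
  pct <- rbind(
    Capital = c(43.4, 2.6, 8.6, 6.9, 1.3, 2.6, 1.3, 3.6, 9.2, 13.8, 3.4, 1.4, 2.0),
    Zealand = c(46.9, 2.5, 8.8, 6.3, 0.5, 1.3, 1.2, 2.1, 10.0, 13.8, 3.3, 1.6, 1.7),
    Central = c(45.7, 3.2, 9.4, 8.1, 0.5, 1.0, 1.2, 2.5, 9.3, 13.1, 3.4, 1.3, 1.2),
    South   = c(45.6, 3.0, 9.4, 7.3, 0.4, 1.6, 1.2, 2.4, 8.8, 13.4, 3.5, 1.4, 2.0),
    North   = c(48.8, 2.3, 8.2, 8.7, 0.6, 1.0, 1.3, 2.3, 9.0, 13.1, 2.8, 0.9, 0.9)
  )
  colnames(pct) <- hgs
  base <- pct / 100
  # trending hgs start at their 1981 national level, scaled by the region's
  # relative level; the published regional values are period averages
  nat_period <- c(L3 = 0.007, M = 0.016, U = 0.135)  # cohort-wide period means
  nat_1981 <- c(L3 = 0.002, M = 0.010, U = 0.127)
  for (hg in names(nat_1981)) {
    base[, hg] <- base[, hg] / nat_period[hg] * nat_1981[hg]
  }
  trend <- c(L3 = 0.0004, M = 0.0006, U = 0.0007)
  weights <- c(Capital = 6818, Zealand = 3550, Central = 5660,
               South = 4957, North = 2632)
  metro <- c(Capital = 0.75, Zealand = 0.15, Central = 0.35,
             South = 0.25, North = 0.30)
  frequency_model(regions, 1981:2005, base, trend, weights, metro)
}

#' Simulate a birth cohort with regional and temporal haplogroup structure
#'
#' Samples are drawn independently: region from the model's sampling weights,
#' birth year uniform over the configured range, metropolitan flag from the
#' region's metro fraction, and the true haplogroup from the region-and-year
#' adjusted frequency vector.
#'
#' @param model a [frequency_model].
#' @param tree a [haplo_tree]; every model haplogroup must be a tree node.
#' @param n number of samples (>= 1).
#' @param seed integer seed; identical `(model, n, seed)` give identical output.
#' @return A `cohort_table` data.frame: `sample_id`, `birth_year`, `region`,
#'   `metro`, `true_hg`.
#' @export
simulate_cohort <- function(model, tree, n, seed) {
  stopifnot(inherits(model, "frequency_model"), n >= 1)
  validate_model_tree(model, tree)
  set.seed(seed)
  region <- sample(model$regions, n, replace = TRUE, prob = model$region_weights)
  year <- sample(model$years, n, replace = TRUE)
  metro <- stats::runif(n) < model$metro_frac[region]
  hgs <- colnames(model$base_freq)
  true_hg <- character(n)
  # draw within (region, year) strata so each stratum uses its own vector
  for (r in model$regions) {
    for (y in model$years) {
      idx <- which(region == r & year == y)
      if (!length(idx)) next
      true_hg[idx] <- sample(hgs, length(idx), replace = TRUE,
                             prob = realized_freq(model, r, y))
    }
  }
  out <- data.frame(sample_id = sprintf("S%06d", seq_len(n)),
                    birth_year = year, region = region, metro = unname(metro),
                    true_hg = true_hg, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Simulate haploid genotypes consistent with a haplogroup tree
#'
#' Each sample carries the derived allele at every defining variant on the
#' root-to-`true_hg` path and the ancestral allele elsewhere; independent
#' private flips are then applied at `private_mut_rate` per locus (never at
#' defining positions of the sample's own path, keeping classification
#' identifiable), and calls are masked to MISSING at `missing_rate`.
#'
#' @param cohort a `cohort_table` from [simulate_cohort()].
#' @param tree a [haplo_tree].
#' @param panel locus panel (data.frame `id`, `position`, `ref`, `alt`); must
#'   cover every defining position on every used path.
#' @param private_mut_rate per-locus probability of a private flip.
#' @param missing_rate per-call probability of masking to MISSING.
#' @param seed integer seed.
#' @return A [genotype_matrix] with one row per cohort sample.
#' @export
simulate_genotypes <- function(cohort, tree, panel, private_mut_rate = 0,
                               missing_rate = 0, seed = 1L) {
  stopifnot(private_mut_rate >= 0, private_mut_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  n <- nrow(cohort)
  L <- nrow(panel)
  used_hgs <- unique(cohort$true_hg)
  # expected call vector (0/1) and defining-position mask per used haplogroup
  base_rows <- matrix(0L, length(used_hgs), L,
                      dimnames = list(used_hgs, panel$id))
  path_mask <- matrix(FALSE, length(used_hgs), L, dimnames = list(used_hgs, NULL))
  for (hg in used_hgs) {
    for (node in tree_path(tree, hg)) {
      v <- tree$variants[[node]]
      if (!nrow(v)) next
      j <- match(v$position, panel$position)
      if (anyNA(j)) {
        stop("panel lacks defining position(s) of node ", node, ": ",
             paste(v$position[is.na(j)], collapse = ", "))
      }
      derived_is_alt <- v$allele == panel$alt[j]
      derived_is_ref <- v$allele == panel$ref[j]
      if (any(!derived_is_alt & !derived_is_ref)) {
        stop("node ", node, ": derived allele not among panel alleles at ",
             paste(v$position[!derived_is_alt & !derived_is_ref], collapse = ", "))
      }
      base_rows[hg, j] <- ifelse(derived_is_alt, 1L, 0L)
      path_mask[hg, j] <- TRUE
    }
  }
  calls <- base_rows[cohort$true_hg, , drop = FALSE]
  protect <- path_mask[cohort$true_hg, , drop = FALSE]
  if (private_mut_rate > 0) {
    flip <- matrix(stats::runif(n * L) < private_mut_rate, n, L) & !protect
    calls[flip] <- 1L - calls[flip]
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n * L) < missing_rate, n, L)
    calls[mask] <- NA_integer_
  }
  rownames(calls) <- cohort$sample_id
  genotype_matrix(calls, panel)
}

#' Simulate normalized array intensities from genotypes
#'
#' The inverse of the caller rules: REF calls draw an allele angle theta from
#' a clipped Gaussian around 0.05 and ALT around 0.95 (sd = `noise_sd`); a
#' fraction `ab_rate` of records is pushed into the heterozygous-looking AB
#' band (theta near 0.5); a fraction `lowintensity_rate` receives a
#' sub-threshold intensity r < 0.08; all other records get r >= 0.08. MISSING
#' input calls are emitted as low-intensity records so that calling
#' round-trips the matrix.
#'
#' @param genotypes a [genotype_matrix].
#' @param noise_sd standard deviation of the theta noise (>= 0).
#' @param lowintensity_rate fraction of records with failing intensity.
#' @param ab_rate fraction of records pushed into the AB band.
#' @param seed integer seed.
#' @return data.frame of intensity records: `sample_id`, `position`, `r`,
#'   `theta`.
#' @export
simulate_intensities <- function(genotypes, noise_sd = 0.03,
                                 lowintensity_rate = 0, ab_rate = 0,
                                 seed = 1L) {
  stopifnot(noise_sd >= 0,
            lowintensity_rate >= 0, lowintensity_rate <= 1,
            ab_rate >= 0, ab_rate <= 1)
  set.seed(seed)
  calls <- genotypes$calls
  n <- nrow(calls); L <- ncol(calls)
  m <- n * L
  call_vec <- as.vector(calls)                      # column-major
  theta <- ifelse(is.na(call_vec) | call_vec == 0L, 0.05, 0.95)
  if (noise_sd > 0) theta <- theta + stats::rnorm(m, 0, noise_sd)
  r <- stats::runif(m, 0.3, 1.5)
  if (ab_rate > 0) {
    ab <- stats::runif(m) < ab_rate
    theta[ab] <- stats::runif(sum(ab), 0.40, 0.60)
  }
  low <- is.na(call_vec)
  if (lowintensity_rate > 0) low <- low | (stats::runif(m) < lowintensity_rate)
  r[low] <- stats::runif(sum(low), 0, 0.079)
  theta <- pmin(pmax(theta, 0), 1)
  data.frame(
    sample_id = rep(rownames(calls), times = L),
    position = rep(genotypes$loci$position, each = n),
    r = r, theta = theta, stringsAsFactors = FALSE
  )
}

#' Write a cohort table as tab-separated text
#'
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#'
#' @param path input path.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}
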