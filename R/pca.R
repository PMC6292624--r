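#' Binary-encode a genotype matrix for multivariate analysis
#'
#' REF becomes 0 and ALT becomes 1. Missing calls are imputed to the locus
#' mean under the default policy (a locus with no non-missing call gets mean
#' 0), or samples/loci can be handled by dropping complete cases. Constant
#' loci are retained with zero variance so matrix dimensionality is stable.
#'
#' @param g a [genotype_matrix].
#' @param missing_policy `"mean"` (default: impute locus mean) or
#'   `"drop_samples"` (keep only samples with complete calls).
#' @return Numeric matrix (samples x loci).
#' @export
encode_binary <- function(g, missing_policy = c("mean", "drop_samples")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(nrow(g$calls) >= 1L)
  m <- g$calls
  storage.mode(m) <- "double"
  if (missing_policy == "drop_samples") {
    keep <- stats::complete.cases(m)
    if (!any(keep)) stop("no complete samples under drop_samples policy")
    return(m[keep, , drop = FALSE])
  }
  if (anyNA(m)) {
    mu <- colMeans(m, na.rm = TRUE)
    mu[is.nan(mu)] <- 0  # all-missing locus: mean defined as 0
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mu[idx[, 2L]]
  }
  m
}

#' Principal components of a binary SNP matrix
#'
#' Column-centered eigendecomposition of the covariance (no variance scaling
#' by default: binary loci, scaling would inflate rare variants). Deterministic
#' up to sign; signs are fixed by making the largest-magnitude loading of each
#' component positive.
#'
#' @param m numeric matrix (samples x loci), e.g. from [encode_binary()].
#' @param k number of components (<= min(samples, loci)).
#' @param scale. logical; scale loci to unit variance before decomposition
#'   (default FALSE).
#' @return A `pca_result`: list with `loadings` (loci x k), `scores`
#'   (samples x k), `var_frac` (length k, fractions of total variance),
#'   `rank` and `zero_variance` (logical per component: beyond-rank flag).
#' @export
run_pca <- function(m, k, scale. = FALSE) {
  stopifnot(k >= 1, k <= min(dim(m)))
  p <- stats::prcomp(m, center = TRUE, scale. = scale.)
  total_var <- sum(p$sdev^2)
  k_avail <- length(p$sdev)
  kk <- min(k, k_avail)
  loadings <- p$rotation[, seq_len(kk), drop = FALSE]
  scores <- p$x[, seq_len(kk), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(kk)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_frac <- if (total_var > 0) p$sdev[seq_len(kk)]^2 / total_var else
    rep(0, kk)
  if (kk < k) {  # requested beyond available: pad with zero-variance comps
    pad <- k - kk
    loadings <- cbind(loadings, matrix(0, nrow(loadings), pad))
    scores <- cbind(scores, matrix(0, nrow(scores), pad))
    var_frac <- c(var_frac, rep(0, pad))
  }
  colnames(loadings) <- colnames(scores) <- paste0("PC", seq_len(k))
  rank_m <- sum(p$sdev^2 > max(p$sdev^2) * 1e-12)
  structure(list(loadings = loadings, scores = scores, var_frac = var_frac,
                 rank = rank_m,
                 zero_variance = seq_len(k) > rank_m),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d samples x %d components; var fractions %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.3f", x$var_frac), collapse = " ")))
  invisible(x)
}

#' Quantitative cluster-separation summary of PCA scores
#'
#' The quantitative counterpart of "the haplogroups separate on PC1/PC2":
#' per-label centroids and dispersions (RMS distance to centroid) on the
#' requested component pairs, plus pairwise centroid distances.
#'
#' @param scores score matrix from [run_pca()].
#' @param labels haplogroup label per sample (same row order).
#' @param pairs list of 2-element integer vectors of component indices
#'   (default PC1/PC2 and PC1/PC3 when available).
#' @return list with `centroids` (data.frame: pair, label, centroid
#'   coordinates, dispersion, n) and `distances` (data.frame: pair, label_a,
#'   label_b, centroid distance).
#' @export
cluster_separation_report <- function(scores, labels,
                                      pairs = NULL) {
  stopifnot(length(labels) == nrow(scores))
  if (is.null(pairs)) {
    pairs <- list(c(1L, 2L))
    if (ncol(scores) >= 3L) pairs <- c(pairs, list(c(1L, 3L)))
  }
  cent_rows <- list(); dist_rows <- list()
  for (pr in pairs) {
    tag <- paste0("PC", pr[1L], "/PC", pr[2L])
    sub <- scores[, pr, drop = FALSE]
    labs <- sort(unique(labels))
    cent <- t(vapply(labs, function(l) colMeans(sub[labels == l, , drop = FALSE]),
                     numeric(2L)))
    disp <- vapply(labs, function(l) {
      s <- sub[labels == l, , drop = FALSE]
      sqrt(mean(rowSums(sweep(s, 2L, colMeans(s))^2)))
    }, 0)
    nlab <- vapply(labs, function(l) sum(labels == l), 0L)
    cent_rows[[tag]] <- data.frame(pair = tag, label = labs,
                                   c1 = cent[, 1L], c2 = cent[, 2L],
                                   dispersion = disp, n = nlab,
                                   stringsAsFactors = FALSE, row.names = NULL)
    if (length(labs) >= 2L) {
      cmb <- utils::combn(labs, 2L)
      d <- vapply(seq_len(ncol(cmb)), function(kk) {
        a <- cent[labs == cmb[1L, kk], , drop = FALSE]
        b <- cent[labs == cmb[2L, kk], , drop = FALSE]
        sqrt(sum((a - b)^2))
      }, 0)
      dist_rows[[tag]] <- data.frame(pair = tag, label_a = cmb[1L, ],
                                     label_b = cmb[2L, ], distance = d,
                                     stringsAsFactors = FALSE)
    }
  }
  list(centroids = do.call(rbind, c(cent_rows, list(make.row.names = FALSE))),
       distances = if (length(dist_rows))
         do.call(rbind, c(dist_rows, list(make.row.names = FALSE))) else
         data.frame(pair = character(), label_a = character(),
                    label_b = character(), distance = numeric(),
                    stringsAsFactors = FALSE))
}
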