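#' Acceptance rule for hierarchical haplogroup classification
#'
#' During greedy root-to-leaf descent, a candidate child is accepted when at
#' least `min_observed` of its panel-covered defining variants are called and
#' the matched fraction reaches the level's threshold: `min_match_frac_macro`
#' for macro-level candidates (strict by default, since a wrong first split is
#' unrecoverable) and `min_match_frac` below. These thresholds are a
#' reproducible surrogate for manual "unequivocal" assignment, which published
#' studies do not state algorithmically.
#'
#' @param min_observed minimum called defining variants (default 1).
#' @param min_match_frac_macro matched/observed threshold at macro level
#'   (default 1.0).
#' @param min_match_frac matched/observed threshold below macro (default 0.5).
#' @return An object of class `classifier_rule`.
#' @export
classifier_rule <- function(min_observed = 1L, min_match_frac_macro = 1.0,
                            min_match_frac = 0.5) {
  stopifnot(min_observed >= 1, min_match_frac_macro >= 0,
            min_match_frac_macro <= 1, min_match_frac >= 0, min_match_frac <= 1)
  structure(list(min_observed = as.integer(min_observed),
                 min_match_frac_macro = min_match_frac_macro,
                 min_match_frac = min_match_frac),
            class = "classifier_rule")
}

# Precompute, per tree node, the matrix columns of its panel-covered defining
# variants and the expected 0/1 call there. Nodes with no covered variants are
# uncallable.
index_tree <- function(tree, loci) {
  idx <- lapply(tree$nodes$name, function(nm) {
    v <- tree$variants[[nm]]
    if (!nrow(v)) {
      return(list(cols = integer(), expect = integer(), uncallable = TRUE))
    }
    j <- match(v$position, loci$position)
    on_panel <- !is.na(j)
    expect <- rep(NA_integer_, nrow(v))
    expect[on_panel & v$allele == loci$alt[j]] <- 1L
    expect[on_panel & v$allele == loci$ref[j]] <- 0L
    keep <- on_panel & !is.na(expect)
    list(cols = j[keep], expect = expect[keep], uncallable = !any(keep))
  })
  names(idx) <- tree$nodes$name
  idx[[tree$root]]$uncallable <- FALSE
  idx
}

#' Score one sample's genotype against a tree node's defining variants
#'
#' Over the node's panel-covered defining variants: `observed` counts
#' non-missing calls, `matched` counts calls equal to the derived allele,
#' `mismatched = observed - matched`.
#'
#' @param genotype integer vector of one sample's calls (0/1/NA), in panel
#'   locus order.
#' @param tree a [haplo_tree].
#' @param node node name.
#' @param panel locus panel matching `genotype`.
#' @return Named integer vector `c(observed, matched, mismatched)`.
#' @export
score_node <- function(genotype, tree, node, panel) {
  ix <- index_tree(tree, panel)[[node]]
  calls <- genotype[ix$cols]
  observed <- sum(!is.na(calls))
  matched <- sum(calls == ix$expect, na.rm = TRUE)
  c(observed = observed, matched = matched, mismatched = observed - matched)
}

# Callable candidate children of `node`, looking through uncallable nodes
# (their callable descendants become direct candidates).
callable_children <- function(tree, idx, node) {
  out <- character()
  for (ch in tree_children(tree, node)) {
    if (idx[[ch]]$uncallable) {
      out <- c(out, callable_children(tree, idx, ch))
    } else {
      out <- c(out, ch)
    }
  }
  out
}

classify_one <- function(calls_row, tree, idx, rule, levels_of) {
  result <- c(macro = NA_character_, hg = NA_character_, subhg = NA_character_)
  diag_rows <- list()
  current <- tree$root
  repeat {
    cand <- callable_children(tree, idx, current)
    if (!length(cand)) break
    best <- NULL
    best_key <- NULL
    for (ch in cand) {
      ix <- idx[[ch]]
      calls <- calls_row[ix$cols]
      obs <- sum(!is.na(calls))
      mat <- sum(calls == ix$expect, na.rm = TRUE)
      lev <- levels_of[[ch]]
      frac_min <- if (identical(lev, "macro")) rule$min_match_frac_macro else rule$min_match_frac
      if (obs < rule$min_observed) next
      frac <- mat / obs
      if (frac < frac_min) next
      # maximize matched/observed; ties: higher matched, then smaller name
      key <- list(frac = frac, matched = mat, name = ch)
      if (is.null(best) ||
          key$frac > best_key$frac + 1e-12 ||
          (abs(key$frac - best_key$frac) <= 1e-12 &&
           (key$matched > best_key$matched ||
            (key$matched == best_key$matched && key$name < best_key$name)))) {
        best <- ch
        best_key <- key
        best_diag <- c(obs, mat, obs - mat)
      }
    }
    if (is.null(best)) break
    lev <- levels_of[[best]]
    if (lev %in% names(result)) result[[lev]] <- best
    diag_rows[[best]] <- best_diag
    current <- best
  }
  status <- if (is.na(result[["macro"]])) {
    "unassigned"
  } else if (is.na(result[["hg"]]) || is.na(result[["subhg"]])) {
    "partial"
  } else {
    "full"
  }
  list(result = result, status = status, diagnostics = diag_rows)
}

#' Classify one sample by hierarchical defining-SNP matching
#'
#' Greedy root-to-leaf descent: at each step, among callable children (looking
#' through uncallable nodes), the child maximizing matched/observed is
#' accepted provided it meets the [classifier_rule]; descent stops when no
#' child qualifies. Back-mutations at already-accepted ancestors are not
#' re-penalized: only each candidate's own defining set is scored.
#'
#' @param genotype integer vector of one sample's calls (0/1/NA) in panel
#'   locus order.
#' @param tree a [haplo_tree].
#' @param panel locus panel matching `genotype`.
#' @param rule a [classifier_rule].
#' @return A one-row data.frame (`hg_call`): `macro_hg`, `hg`, `sub_hg`
#'   (NA = unassigned) and `status` in full/partial/unassigned.
#' @export
classify_sample <- function(genotype, tree, panel, rule = classifier_rule()) {
  idx <- index_tree(tree, panel)
  levels_of <- stats::setNames(as.list(tree$nodes$level), tree$nodes$name)
  res <- classify_one(genotype, tree, idx, rule, levels_of)
  data.frame(macro_hg = res$result[["macro"]], hg = res$result[["hg"]],
             sub_hg = res$result[["subhg"]], status = res$status,
             stringsAsFactors = FALSE)
}

#' Classify every sample of a genotype matrix
#'
#' @param g a [genotype_matrix].
#' @param tree a [haplo_tree].
#' @param rule a [classifier_rule].
#' @return list with `calls` (data.frame: `sample_id`, `macro_hg`, `hg`,
#'   `sub_hg`, `status`) and `summary` (per-level unassigned fractions).
#' @export
classify_cohort <- function(g, tree, rule = classifier_rule()) {
  n <- nrow(g$calls)
  if (n == 0L) {
    empty <- data.frame(sample_id = character(), macro_hg = character(),
                        hg = character(), sub_hg = character(),
                        status = character(), stringsAsFactors = FALSE)
    return(list(calls = empty,
                summary = c(macro = NaN, hg = NaN, subhg = NaN)))
  }
  idx <- index_tree(tree, g$loci)
  levels_of <- stats::setNames(as.list(tree$nodes$level), tree$nodes$name)
  macro <- hg <- sub <- rep(NA_character_, n)
  status <- character(n)
  for (i in seq_len(n)) {
    res <- classify_one(g$calls[i, ], tree, idx, rule, levels_of)
    macro[i] <- res$result[["macro"]]
    hg[i] <- res$result[["hg"]]
    sub[i] <- res$result[["subhg"]]
    status[i] <- res$status
  }
  calls <- data.frame(sample_id = rownames(g$calls), macro_hg = macro,
                      hg = hg, sub_hg = sub, status = status,
                      stringsAsFactors = FALSE)
  list(calls = calls,
       summary = c(macro = mean(is.na(macro)), hg = mean(is.na(hg)),
                   subhg = mean(is.na(sub))))
}

#' Haplogroup label of a call at a reporting level, with fallback
#'
#' Published tables report each sample at the deepest level available: a
#' sample resolved only to macro R appears in the "R" row of an hg-level
#' table. `label_at_level` reproduces that: at level `hg` the hg label is used
#' when assigned, otherwise the macro label, otherwise `NA`.
#'
#' @param calls hg-call data.frame from [classify_cohort()].
#' @param level one of "macro", "hg", "subhg".
#' @param collapse optional named character vector mapping labels onto
#'   reporting bins (e.g. `c(L0 = "L", L3 = "L")`).
#' @return Character vector of labels (NA where unassigned at every usable
#'   level).
#' @export
label_at_level <- function(calls, level = c("hg", "macro", "subhg"),
                           collapse = NULL) {
  level <- match.arg(level)
  lab <- switch(level,
    macro = calls$macro_hg,
    hg = ifelse(!is.na(calls$hg), calls$hg, calls$macro_hg),
    subhg = ifelse(!is.na(calls$sub_hg), calls$sub_hg,
                   ifelse(!is.na(calls$hg), calls$hg, calls$macro_hg))
  )
  if (!is.null(collapse)) {
    hit <- lab %in% names(collapse)
    lab[hit] <- collapse[lab[hit]]
  }
  lab
}

#' Write haplogroup calls as tab-separated text
#'
#' @param calls hg-call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hg_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
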