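#' Haplogroup trees of defining SNPs
#'
#' A `haplo_tree` is a rooted hierarchy of named haplogroup nodes. Each node
#' carries a set of defining variants (1-based rCRS position plus derived
#' allele) and a level tag: `"macro"` (the deepest splits, L0-L6 / M / N / R),
#' `"hg"` (e.g. H, U, T) or `"subhg"` (e.g. H1, U5a). The root ("mt-MRCA")
#' has no parent and no defining variants.
#'
#' @param nodes data.frame with columns `name`, `parent` (NA for the root) and
#'   `level` (one of `"macro"`, `"hg"`, `"subhg"`; the root may carry `"root"`).
#' @param variants named list (one entry per node name) of data.frames with
#'   columns `position` (integer, 1-based rCRS) and `allele` (derived base).
#' @return An object of class `haplo_tree`.
#' @export
haplo_tree <- function(nodes, variants) {
  stopifnot(is.data.frame(nodes), all(c("name", "parent", "level") %in% names(nodes)))
  nodes$name <- as.character(nodes$name)
  nodes$parent <- as.character(nodes$parent)
  nodes$level <- as.character(nodes$level)
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  root <- nodes$name[is.na(nodes$parent)]
  if (length(root) != 1L) {
    stop("tree must have exactly one root (node with no parent); found ",
         length(root))
  }
  bad_parent <- setdiff(nodes$parent[!is.na(nodes$parent)], nodes$name)
  if (length(bad_parent)) {
    stop("orphan parent reference(s): ", paste(bad_parent, collapse = ", "))
  }
  # cycle check: walk every node to the root
  parent_of <- stats::setNames(nodes$parent, nodes$name)
  for (nm in nodes$name) {
    seen <- character()
    cur <- nm
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop("cycle detected at node ", nm)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  variants <- variants[nodes$name[nodes$name %in% names(variants)]]
  for (nm in setdiff(nodes$name, names(variants))) {
    variants[[nm]] <- data.frame(position = integer(), allele = character(),
                                 stringsAsFactors = FALSE)
  }
  for (nm in names(variants)) {
    v <- variants[[nm]]
    stopifnot(all(c("position", "allele") %in% names(v)))
    v$position <- as.integer(v$position)
    v$allele <- as.character(v$allele)
    if (any(is.na(v$position)) || any(!nzchar(v$allele))) {
      stop("node ", nm, ": every defining variant needs a position and a ",
           "concrete derived allele")
    }
    variants[[nm]] <- v
  }
  structure(list(nodes = nodes, variants = variants[nodes$name], root = root),
            class = "haplo_tree")
}

#' Read a haplogroup tree from a tab-separated node file
#'
#' One node per line with four columns: node name, parent name (`-` or empty
#' for the root), level tag, and a comma-separated list of defining variants
#' written as `position:allele` (empty for nodes without covered variants).
#'
#' @param path path to the tree file.
#' @return A validated [haplo_tree].
#' @export
load_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "parent", "level", "variants")
  if (!all(need %in% names(raw))) {
    stop("tree file must have columns: ", paste(need, collapse = ", "))
  }
  raw$parent[raw$parent %in% c("", "-", "NA")] <- NA_character_
  variants <- lapply(raw$variants, function(s) {
    s <- trimws(s)
    if (!nzchar(s)) {
      return(data.frame(position = integer(), allele = character(),
                        stringsAsFactors = FALSE))
    }
    parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("malformed variant spec: ", s)
    data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
               allele = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  })
  names(variants) <- raw$name
  haplo_tree(raw[c("name", "parent", "level")], variants)
}

#' Write a haplogroup tree to the tab-separated node format
#'
#' @param tree a [haplo_tree].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  vs <- vapply(tree$variants, function(v) {
    paste(sprintf("%d:%s", v$position, v$allele), collapse = ",")
  }, "")
  out <- tree$nodes
  out$parent[is.na(out$parent)] <- "-"
  out$variants <- vs[out$name]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.haplo_tree <- function(x, ...) {
  cat("haplo_tree:", nrow(x$nodes), "nodes, root", x$root, "\n")
  cat("levels:", paste(sprintf("%s=%d", names(table(x$nodes$level)),
                               table(x$nodes$level)), collapse = " "), "\n")
  invisible(x)
}

tree_children <- function(tree, name) {
  tree$nodes$name[!is.na(tree$nodes$parent) & tree$nodes$parent == name]
}

#' Root-to-node path of a haplogroup node
#'
#' @param tree a [haplo_tree].
#' @param name node name.
#' @return Character vector of node names from the root down to `name`.
#' @export
tree_path <- function(tree, name) {
  if (!name %in% tree$nodes$name) stop("unknown haplogroup label: ", name)
  parent_of <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  path <- name
  while (!is.na(parent_of[[path[1L]]])) path <- c(parent_of[[path[1L]]], path)
  path
}

#' Flag tree nodes with no panel-covered defining variants
#'
#' A node is callable only if at least one of its defining variants sits at a
#' panel position whose ref/alt alleles include the derived allele. Uncallable
#' nodes (e.g. HV when its diagnostic SNPs are off-array) are transparent
#' during classification: samples route through them to deeper callable nodes
#' or stay at the parent.
#'
#' @param tree a [haplo_tree].
#' @param panel data.frame with columns `position`, `ref`, `alt`.
#' @return The tree with a logical `uncallable` column added to `$nodes`.
#' @export
mark_uncallable <- function(tree, panel) {
  covered <- function(nm) {
    v <- tree$variants[[nm]]
    if (nrow(v) == 0L) return(FALSE)
    i <- match(v$position, panel$position)
    any(!is.na(i) & (v$allele == panel$ref[i] | v$allele == panel$alt[i]))
  }
  unc <- !vapply(tree$nodes$name, covered, TRUE)
  unc[tree$nodes$name == tree$root] <- FALSE  # root needs no variants
  tree$nodes$uncallable <- unname(unc)
  tree
}

#' Bundled synthetic haplogroup tree
#'
#' Returns a small synthetic stand-in for a PhyloTree-style hierarchy, with
#' the macro / hg / sub-hg label set used in published Danish cohort tables
#' (root mt-MRCA; macros L0-L6, M, N, R; the common European hgs under R;
#' a few sub-hgs). Defining positions are invented coordinates in the rCRS
#' range; every node carries two or three private defining variants so that
#' noise-free classification is exact.
#'
#' The same tree ships as a file at
#' `system.file("extdata", "haplotree_synthetic.tsv", package = "mitocline")`.
#'
#' @return A [haplo_tree].
#' @export
example_haplo_tree <- function() {
  spec <- list(
    # name, parent, level
    c("mt-MRCA", NA, "root"),
    c("L0", "mt-MRCA", "macro"), c("L1", "mt-MRCA", "macro"),
    c("L2", "mt-MRCA", "macro"), c("L3", "mt-MRCA", "macro"),
    c("L4", "mt-MRCA", "macro"), c("L5", "mt-MRCA", "macro"),
    c("L6", "mt-MRCA", "macro"),
    c("M", "mt-MRCA", "macro"), c("N", "mt-MRCA", "macro"),
    c("R", "mt-MRCA", "macro"),
    # under M
    c("C", "M", "hg"), c("D4", "M", "hg"), c("G", "M", "hg"),
    c("M1", "M", "hg"), c("Z", "M", "hg"),
    # under N
    c("A", "N", "hg"), c("I", "N", "hg"), c("W", "N", "hg"),
    c("X", "N", "hg"), c("Y", "N", "hg"),
    # under R
    c("H", "R", "hg"), c("V", "R", "hg"), c("U", "R", "hg"),
    c("K", "R", "hg"), c("T", "R", "hg"), c("J", "R", "hg"),
    c("F", "R", "hg"), c("B", "R", "hg"),
    # sub-hgs
    c("H1", "H", "subhg"), c("H2", "H", "subhg"), c("H3", "H", "subhg"),
    c("H4", "H", "subhg"), c("H5", "H", "subhg"),
    c("U1", "U", "subhg"), c("U2", "U", "subhg"), c("U4", "U", "subhg"),
    c("U5a", "U", "subhg"), c("U5b", "U", "subhg"), c("U6", "U", "subhg"),
    c("U7", "U", "subhg"), c("U8", "U", "subhg"),
    c("K1", "K", "subhg"), c("K2", "K", "subhg"),
    c("J1", "J", "subhg"), c("J2", "J", "subhg"),
    c("T1", "T", "subhg"), c("T2", "T", "subhg")
  )
  nodes <- data.frame(name = vapply(spec, `[`, "", 1L),
                      parent = vapply(spec, `[`, "", 2L),
                      level = vapply(spec, `[`, "", 3L),
                      stringsAsFactors = FALSE)
  # deterministic invented positions: 3 per non-root node, spread over the
  # rCRS coordinate range, all distinct
  non_root <- nodes$name[nodes$name != "mt-MRCA"]
  n_var <- 3L
  pos_pool <- seq(101L, by = 37L, length.out = length(non_root) * n_var)
  variants <- list()
  for (i in seq_along(non_root)) {
    p <- pos_pool[((i - 1L) * n_var + 1L):(i * n_var)]
    variants[[non_root[i]]] <- data.frame(position = p,
                                          allele = rep("G", n_var),
                                          stringsAsFactors = FALSE)
  }
  haplo_tree(nodes, variants)
}

#' Locus panel covering a haplogroup tree
#'
#' Builds an array-style locus panel (MAP-like table) containing every
#' defining position of the tree plus filler loci up to `n_loci`, with the
#' ancestral allele as `ref` ("A") and the derived allele as `alt`.
#'
#' @param tree a [haplo_tree].
#' @param n_loci total panel size (default 418, the mtDNA content of the
#'   genotyping array the pipeline targets).
#' @return data.frame with columns `id`, `position`, `ref`, `alt`.
#' @export
panel_for_tree <- function(tree, n_loci = 418L) {
  def_pos <- sort(unique(unlist(lapply(tree$variants, `[[`, "position"))))
  def_allele <- rep("G", length(def_pos))
  # honour per-node alleles (all "G" in the bundled tree, but files may vary)
  for (v in tree$variants) {
    if (nrow(v)) def_allele[match(v$position, def_pos)] <- v$allele
  }
  if (n_loci < length(def_pos)) {
    stop("n_loci (", n_loci, ") smaller than the number of defining positions (",
         length(def_pos), ")")
  }
  n_fill <- n_loci - length(def_pos)
  fill_pos <- integer(0)
  if (n_fill > 0L) {
    cand <- setdiff(seq(16569L, by = -11L, length.out = 1500L), def_pos)
    fill_pos <- sort(cand[seq_len(n_fill)])
  }
  pos <- c(def_pos, fill_pos)
  alt <- c(def_allele, rep("G", n_fill))
  ord <- order(pos)
  pos <- pos[ord]; alt <- alt[ord]
  data.frame(id = sprintf("mt%05d", pos), position = pos,
             ref = "A", alt = alt, stringsAsFactors = FALSE)
}
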