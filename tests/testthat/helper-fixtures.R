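# Shared fixtures and independent oracles, all built in code.

# Small three-level tree: root -> {R, M}; R -> {H, U}; H -> {H1}; U -> {U5a}.
# Each node has `k` private defining positions, derived allele = alt ("G").
toy_tree <- function(k = 2L) {
  nodes <- data.frame(
    name = c("root", "R", "M", "H", "U", "H1", "U5a"),
    parent = c(NA, "root", "root", "R", "R", "H", "U"),
    level = c("root", "macro", "macro", "hg", "hg", "subhg", "subhg"),
    stringsAsFactors = FALSE
  )
  non_root <- nodes$name[-1L]
  variants <- list()
  pos <- 10L
  for (nm in non_root) {
    variants[[nm]] <- data.frame(position = pos + seq_len(k) - 1L,
                                 allele = "G", stringsAsFactors = FALSE)
    pos <- pos + k
  }
  haplo_tree(nodes, variants)
}

toy_panel <- function(tree, n_loci = 30L) panel_for_tree(tree, n_loci)

# Single-region model over a tree's leaf-ish labels.
toy_model <- function(hgs, props, years = 1981:2005, trend = numeric()) {
  bf <- matrix(props, nrow = 1L, dimnames = list("OnlyRegion", hgs))
  frequency_model("OnlyRegion", years, bf, trend = trend,
                  metro_frac = c(OnlyRegion = 0.5))
}

# Random tree generator for oracle-equivalence tests: random topology with
# `n_nodes` nodes under a root, random levels consistent with depth, 1-3
# private defining positions per node.
random_tree <- function(n_nodes, seed) {
  set.seed(seed)
  names_all <- c("root", paste0("N", seq_len(n_nodes)))
  parent <- c(NA_character_, vapply(seq_len(n_nodes), function(i) {
    names_all[sample.int(i, 1L)]  # parent among earlier nodes
  }, ""))
  depth <- integer(n_nodes + 1L)
  for (i in 2L:(n_nodes + 1L)) {
    depth[i] <- depth[match(parent[i], names_all)] + 1L
  }
  level <- c("root", c("macro", "hg", "subhg")[pmin(depth[-1L], 3L)])
  pos <- 100L
  variants <- list()
  for (i in 2L:(n_nodes + 1L)) {
    k <- sample(1:3, 1L)
    variants[[names_all[i]]] <- data.frame(
      position = pos + seq_len(k) - 1L, allele = "G", stringsAsFactors = FALSE)
    pos <- pos + k
  }
  haplo_tree(data.frame(name = names_all, parent = parent, level = level,
                        stringsAsFactors = FALSE), variants)
}

# Exhaustive classifier oracle: scores every root-to-node path and picks the
# deepest path whose every step satisfies the rule, with the same step-wise
# child choice (max frac, then matched, then name) applied independently of
# the greedy code path.
oracle_classify <- function(genotype, tree, panel, rule = classifier_rule()) {
  score <- function(node) {
    v <- tree$variants[[node]]
    if (!nrow(v)) return(c(obs = 0L, mat = 0L))
    j <- match(v$position, panel$position)
    ok <- !is.na(j) & (v$allele == panel$alt[j] | v$allele == panel$ref[j])
    j <- j[ok]
    expect <- as.integer(tree$variants[[node]]$allele[ok] == panel$alt[j])
    calls <- genotype[j]
    c(obs = sum(!is.na(calls)), mat = sum(calls == expect, na.rm = TRUE))
  }
  callable <- vapply(tree$nodes$name, function(nm) {
    v <- tree$variants[[nm]]
    if (!nrow(v)) return(FALSE)
    j <- match(v$position, panel$position)
    any(!is.na(j) & (v$allele == panel$alt[j] | v$allele == panel$ref[j]))
  }, TRUE)
  names(callable) <- tree$nodes$name
  callable[tree$root] <- TRUE
  qualifies <- function(node) {
    s <- score(node)
    lev <- tree$nodes$level[tree$nodes$name == node]
    fr <- if (identical(lev, "macro")) rule$min_match_frac_macro else rule$min_match_frac
    s[["obs"]] >= rule$min_observed && s[["mat"]] / s[["obs"]] >= fr
  }
  # candidate children looking through uncallable nodes
  cand_children <- function(node) {
    out <- character()
    for (ch in tree$nodes$name[!is.na(tree$nodes$parent) &
                               tree$nodes$parent == node]) {
      if (callable[[ch]]) out <- c(out, ch) else out <- c(out, cand_children(ch))
    }
    out
  }
  path <- character()
  cur <- tree$root
  repeat {
    cands <- Filter(qualifies, cand_children(cur))
    if (!length(cands)) break
    ss <- lapply(cands, score)
    frac <- vapply(ss, function(s) s[["mat"]] / s[["obs"]], 0)
    mat <- vapply(ss, function(s) s[["mat"]], 0L)
    best <- order(-frac, -mat, cands)[1L]
    cur <- cands[best]
    path <- c(path, cur)
  }
  res <- c(macro = NA_character_, hg = NA_character_, subhg = NA_character_)
  for (nd in path) {
    lev <- tree$nodes$level[tree$nodes$name == nd]
    if (lev %in% names(res)) res[[lev]] <- nd
  }
  res
}

# Brute-force quasi-median closure of a 0/1 haplotype matrix.
qm_closure <- function(vecs) {
  keys <- function(m) apply(m, 1L, paste, collapse = "")
  cur <- unique(vecs)
  repeat {
    n <- nrow(cur)
    have <- keys(cur)
    added <- FALSE
    if (n >= 3L) for (a in 1:(n - 2L)) for (b in (a + 1L):(n - 1L)) for (cc in (b + 1L):n) {
      qm <- as.integer((cur[a, ] + cur[b, ] + cur[cc, ]) >= 2L)
      if (!(paste(qm, collapse = "") %in% have)) {
        cur <- rbind(cur, qm)
        have <- c(have, paste(qm, collapse = ""))
        added <- TRUE
      }
    }
    if (!added) return(cur)
  }
}

# Independent MST oracle over Hamming distances (igraph).
oracle_mst_weight <- function(vecs) {
  D <- as.matrix(stats::dist(vecs, method = "manhattan"))
  g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                           mode = "undirected")
  sum(igraph::E(igraph::mst(g))$weight)
}

# Path haplotype (0/1 vector over a panel) of a tree node.
path_vector <- function(tree, panel, hg) {
  v <- rep(0L, nrow(panel))
  for (nd in tree_path(tree, hg)) {
    p <- tree$variants[[nd]]
    if (nrow(p)) v[match(p$position, panel$position)] <- 1L
  }
  v
}
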