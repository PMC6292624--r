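#' Sets of distinct binary haplotypes with multiplicities
#'
#' @param vectors integer/numeric matrix over {0,1}; one row per distinct
#'   haplotype.
#' @param mult positive integer multiplicities, one per row.
#' @param labels optional row labels; default is the 0/1 string of each row.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(vectors, mult = rep(1L, nrow(vectors)),
                          labels = NULL) {
  vectors <- as.matrix(vectors)
  storage.mode(vectors) <- "integer"
  if (!all(vectors %in% c(0L, 1L))) stop("haplotype vectors must be 0/1")
  if (length(mult) != nrow(vectors)) stop("one multiplicity per haplotype")
  if (any(mult < 1)) stop("multiplicities must be >= 1")
  keys <- apply(vectors, 1L, paste, collapse = "")
  if (anyDuplicated(keys)) stop("haplotypes must be distinct")
  if (is.null(labels)) labels <- keys
  rownames(vectors) <- labels
  structure(list(vectors = vectors, mult = as.integer(mult), labels = labels),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("haplotype_set: %d haplotypes of length %d, %d samples\n",
              nrow(x$vectors), ncol(x$vectors), sum(x$mult)))
  invisible(x)
}

hamming <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  g <- tcrossprod(m)
  ones <- tcrossprod(1 - m)
  d <- outer(diag(g), diag(g), "+") - 2 * g
  round(d)
}

#' Drop rare haplotypes before network construction
#'
#' Mirrors the "Frequency > 1" preprocessing option of network software:
#' haplotypes observed fewer than `min_count` times are removed.
#'
#' @param h a [haplotype_set].
#' @param min_count minimum multiplicity to keep (>= 1; the published setting
#'   keeps multiplicity > 1, i.e. `min_count = 2`).
#' @return A filtered [haplotype_set]; an error if nothing survives.
#' @export
frequency_filter <- function(h, min_count) {
  stopifnot(min_count >= 1)
  keep <- h$mult >= min_count
  if (!any(keep)) stop("frequency filter removed every haplotype")
  haplotype_set(h$vectors[keep, , drop = FALSE], h$mult[keep],
                h$labels[keep])
}

#' Star-contraction preprocessing
#'
#' Iteratively collapses star-like clusters: a satellite haplotype within
#' Hamming distance `max_radius` of a center, and strictly closer to that
#' center than to any other haplotype, is merged into the center with summed
#' multiplicity. Iterated to a fixed point; every merge is logged.
#'
#' @param h a [haplotype_set].
#' @param max_radius maximum star radius in mutation counts (>= 1; published
#'   settings: 5 for the R/N/M macro-hgs, 1 for L).
#' @return list with `set` (contracted [haplotype_set]) and `log` (data.frame
#'   `round`, `center`, `satellite`, `distance`, `mult_absorbed`).
#' @export
star_contraction <- function(h, max_radius) {
  stopifnot(max_radius >= 1)
  log_rows <- list()
  round_i <- 0L
  repeat {
    n <- nrow(h$vectors)
    if (n < 2L) break
    round_i <- round_i + 1L
    D <- hamming(h$vectors)
    diag(D) <- Inf
    # satellite i -> center j: j is i's unique nearest neighbour within radius
    target <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      dmin <- min(D[i, ])
      if (dmin > max_radius) next
      nearest <- which(D[i, ] == dmin)
      if (length(nearest) == 1L) target[i] <- nearest
    }
    is_center <- seq_len(n) %in% target[!is.na(target)]
    # a node that is itself a center keeps its own star this round
    sat <- which(!is.na(target) & !is_center)
    sat <- sat[is_center[target[sat]] | TRUE]  # all non-center satellites merge
    if (!length(sat)) break
    for (i in sat) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        round = round_i, center = h$labels[target[i]],
        satellite = h$labels[i], distance = D[i, target[i]],
        mult_absorbed = h$mult[i], stringsAsFactors = FALSE)
    }
    add <- tapply(h$mult[sat], target[sat], sum)
    mult <- h$mult
    mult[as.integer(names(add))] <- mult[as.integer(names(add))] + as.integer(add)
    keep <- setdiff(seq_len(n), sat)
    h <- haplotype_set(h$vectors[keep, , drop = FALSE], mult[keep],
                       h$labels[keep])
  }
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(round = integer(), center = character(), satellite = character(),
               distance = numeric(), mult_absorbed = integer(),
               stringsAsFactors = FALSE)
  list(set = h, log = log_df)
}

# Minimum spanning tree over the complete Hamming graph, deterministic
# (Kruskal; edges sorted by weight, then by endpoint labels).
mst_edges <- function(D, labels) {
  n <- nrow(D)
  if (n == 1L) {
    return(data.frame(i = integer(), j = integer(), w = numeric()))
  }
  idx <- which(upper.tri(D), arr.ind = TRUE)
  e <- data.frame(i = idx[, 1L], j = idx[, 2L], w = D[idx])
  e <- e[order(e$w, labels[e$i], labels[e$j]), , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  keep <- logical(nrow(e))
  for (k in seq_len(nrow(e))) {
    ri <- find(e$i[k]); rj <- find(e$j[k])
    if (ri != rj) { parent[ri] <- rj; keep[k] <- TRUE }
  }
  e[keep, , drop = FALSE]
}

# Minimax (bottleneck) distances between all pairs: max edge weight on the
# unique MST path.
minimax_from_mst <- function(mst, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(mst))) {
    adj[[mst$i[k]]] <- rbind(adj[[mst$i[k]]], c(mst$j[k], mst$w[k]))
    adj[[mst$j[k]]] <- rbind(adj[[mst$j[k]]], c(mst$i[k], mst$w[k]))
  }
  M <- matrix(0, n, n)
  for (s in seq_len(n)) {
    # DFS from s carrying the running max edge weight
    stack <- list(c(s, 0))
    visited <- logical(n); visited[s] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1L]; mx <- top[2L]
      M[s, v] <- mx
      nb <- adj[[v]]
      if (!is.null(nb)) for (k in seq_len(nrow(nb))) {
        u <- nb[k, 1L]
        if (!visited[u]) {
          visited[u] <- TRUE
          stack[[length(stack) + 1L]] <- c(u, max(mx, nb[k, 2L]))
        }
      }
    }
  }
  M
}

# Links of the epsilon-relaxed minimum spanning network: all pairs whose
# direct distance is within epsilon of their bottleneck (first-connection)
# distance.
msn_links <- function(vectors, labels, epsilon) {
  n <- nrow(vectors)
  D <- hamming(vectors)
  if (n == 1L) {
    return(list(D = D, links = matrix(FALSE, 1L, 1L)))
  }
  mst <- mst_edges(D, labels)
  M <- minimax_from_mst(mst, n)
  links <- D <= M + epsilon
  diag(links) <- FALSE
  list(D = D, links = links)
}

quasi_median <- function(a, b, c) {
  s <- a + b + c
  as.integer(s >= 2L)
}

#' Median-joining haplotype network
#'
#' Iterative median-joining over binary haplotypes with unit site weights:
#' compute the epsilon-relaxed minimum spanning network (all links whose cost
#' is within `epsilon` of the cost at which their endpoints first connect);
#' for every connected triplet (at least two of its three pairs linked) add
#' the quasi-median (majority state per position) as an inferred node when
#' new; recompute until closure. Superfluous median nodes — those whose
#' removal changes no shortest-path distance between observed haplotypes — are
#' then deleted. Triplets are processed in sorted label order, so the result
#' is deterministic.
#'
#' @param h a [haplotype_set] (>= 1 haplotype).
#' @param epsilon non-negative integer relaxation in mutation-count units
#'   (published setting: 10).
#' @return An `mj_graph`: list with `vectors` (rows = nodes), `mult`
#'   (0 for inferred medians), `median` (logical), `labels`, `edges`
#'   (data.frame `from`, `to`, `weight`, `positions` comma-separated differing
#'   positions) and `params`.
#' @export
build_mj <- function(h, epsilon = 0L) {
  stopifnot(inherits(h, "haplotype_set"), epsilon >= 0)
  vecs <- h$vectors
  mult <- h$mult
  labels <- h$labels
  is_median <- rep(FALSE, nrow(vecs))
  key <- function(m) apply(m, 1L, paste, collapse = "")
  repeat {
    ord <- order(labels)
    vecs <- vecs[ord, , drop = FALSE]
    mult <- mult[ord]; labels <- labels[ord]; is_median <- is_median[ord]
    net <- msn_links(vecs, labels, epsilon)
    links <- net$links
    n <- nrow(vecs)
    have <- key(vecs)
    new_medians <- list()
    if (n >= 3L) {
      for (a in seq_len(n - 2L)) for (b in (a + 1L):(n - 1L)) for (cc in (b + 1L):n) {
        nlink <- links[a, b] + links[a, cc] + links[b, cc]
        if (nlink < 2L) next
        qm <- quasi_median(vecs[a, ], vecs[b, ], vecs[cc, ])
        k <- paste(qm, collapse = "")
        if (!(k %in% have) && is.null(new_medians[[k]])) new_medians[[k]] <- qm
      }
    }
    if (!length(new_medians)) break
    add <- do.call(rbind, new_medians)
    vecs <- rbind(vecs, add)
    mult <- c(mult, rep(0L, nrow(add)))
    labels <- c(labels, paste0("mv_", names(new_medians)))
    is_median <- c(is_median, rep(TRUE, nrow(add)))
  }
  # obsolete-median cleanup: a median vector of degree <= 2 in the current
  # network is a shortcut the triangle inequality makes redundant (the direct
  # link between its neighbours never costs more), so it is dropped and the
  # network recomputed; medians of degree >= 3 are genuine Steiner nodes
  repeat {
    net <- msn_links(vecs, labels, epsilon)
    deg <- rowSums(net$links)
    drop <- which(is_median & deg <= 2L)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(vecs)), drop[1L])
    vecs <- vecs[keep, , drop = FALSE]
    mult <- mult[keep]; labels <- labels[keep]; is_median <- is_median[keep]
  }
  net <- msn_links(vecs, labels, epsilon)
  edges <- links_to_edges(net, vecs, labels)
  structure(list(vectors = vecs, mult = mult, median = is_median,
                 labels = labels, edges = edges,
                 params = list(epsilon = epsilon)),
            class = "mj_graph")
}

graph_from_links <- function(net, labels) {
  idx <- which(net$links & upper.tri(net$links), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = length(labels), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.vector(t(cbind(idx[, 1L], idx[, 2L]))))
    g <- igraph::set_edge_attr(g, "weight", value = net$D[idx])
  }
  g
}

links_to_edges <- function(net, vecs, labels) {
  idx <- which(net$links & upper.tri(net$links), arr.ind = TRUE)
  if (!nrow(idx)) {
    return(data.frame(from = character(), to = character(), weight = numeric(),
                      positions = character(), stringsAsFactors = FALSE))
  }
  pos <- vapply(seq_len(nrow(idx)), function(k) {
    paste(which(vecs[idx[k, 1L], ] != vecs[idx[k, 2L], ]), collapse = ",")
  }, "")
  out <- data.frame(from = labels[idx[, 1L]], to = labels[idx[, 2L]],
                    weight = net$D[idx], positions = pos,
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' @export
print.mj_graph <- function(x, ...) {
  cat(sprintf("mj_graph: %d nodes (%d observed, %d median), %d edges\n",
              nrow(x$vectors), sum(!x$median), sum(x$median), nrow(x$edges)))
  invisible(x)
}

mj_igraph <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = g$labels, mult = g$mult, median = g$median))
  ig
}

#' Maximum-parsimony post-processing of a median-joining network
#'
#' Deletes every median node and edge that participates in no
#' minimum-total-length spanning subgraph connecting all observed haplotypes.
#' Exhaustive over median-node subsets when the network has at most
#' `exhaustive_limit` nodes; above that a greedy pruning heuristic is used and
#' flagged in `$params$mp_mode`. Observed nodes are never deleted.
#'
#' @param g an `mj_graph` (connected).
#' @param exhaustive_limit switch point between exhaustive and heuristic
#'   search (default 12 nodes).
#' @return The pruned `mj_graph`.
#' @export
mp_postprocess <- function(g, exhaustive_limit = 12L) {
  n <- nrow(g$vectors)
  obs <- which(g$mult > 0L)
  med <- which(g$mult == 0L)
  edge_i <- match(g$edges$from, g$labels)
  edge_j <- match(g$edges$to, g$labels)
  w <- g$edges$weight

  subgraph_mst <- function(nodes) {
    # MST cost of g's edge set restricted to `nodes`; NULL if disconnected
    sel <- which(edge_i %in% nodes & edge_j %in% nodes)
    if (!length(sel) && length(nodes) > 1L) return(NULL)
    ord <- sel[order(w[sel], g$edges$from[sel], g$edges$to[sel])]
    parent <- stats::setNames(nodes, as.character(nodes))
    find <- function(x) {
      x <- as.character(x)
      while (parent[[x]] != as.numeric(x)) x <- as.character(parent[[x]])
      as.numeric(x)
    }
    cost <- 0; used <- integer(); cnt <- 0L
    for (k in ord) {
      ri <- find(edge_i[k]); rj <- find(edge_j[k])
      if (ri != rj) {
        parent[[as.character(ri)]] <- rj
        cost <- cost + w[k]; used <- c(used, k); cnt <- cnt + 1L
      }
    }
    if (cnt != length(nodes) - 1L) return(NULL)
    list(cost = cost, used = used)
  }

  # edges that belong to SOME MST of the node-induced subgraph
  mst_eligible_edges <- function(nodes) {
    sel <- which(edge_i %in% nodes & edge_j %in% nodes)
    elig <- integer()
    for (k in sel) {
      lighter <- sel[w[sel] < w[k]]
      # connected via strictly lighter edges?
      parent <- stats::setNames(nodes, as.character(nodes))
      find <- function(x) {
        x <- as.character(x)
        while (parent[[x]] != as.numeric(x)) x <- as.character(parent[[x]])
        as.numeric(x)
      }
      for (e in lighter) {
        ri <- find(edge_i[e]); rj <- find(edge_j[e])
        if (ri != rj) parent[[as.character(ri)]] <- rj
      }
      if (find(edge_i[k]) != find(edge_j[k])) elig <- c(elig, k)
    }
    elig
  }

  if (n <= exhaustive_limit) {
    best_cost <- Inf
    optimal_subsets <- list()
    m <- length(med)
    for (mask in 0:(2^m - 1L)) {
      S <- med[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L]
      res <- subgraph_mst(c(obs, S))
      if (is.null(res)) next
      if (res$cost < best_cost - 1e-9) {
        best_cost <- res$cost
        optimal_subsets <- list(S)
      } else if (res$cost <= best_cost + 1e-9) {
        optimal_subsets[[length(optimal_subsets) + 1L]] <- S
      }
    }
    if (!length(optimal_subsets)) stop("network does not connect the observed haplotypes")
    keep_nodes <- sort(unique(c(obs, unlist(optimal_subsets))))
    keep_edges <- sort(unique(unlist(lapply(optimal_subsets, function(S) {
      mst_eligible_edges(c(obs, S))
    }))))
    mode <- "exhaustive"
  } else {
    nodes <- seq_len(n)
    base <- subgraph_mst(nodes)
    if (is.null(base)) stop("network is disconnected")
    for (m_i in med) {
      cand <- setdiff(nodes, m_i)
      res <- subgraph_mst(cand)
      if (!is.null(res) && res$cost <= base$cost + 1e-9) {
        nodes <- cand
        base <- res
      }
    }
    keep_nodes <- nodes
    keep_edges <- mst_eligible_edges(nodes)
    mode <- "heuristic"
  }
  sel_e <- keep_edges[edge_i[keep_edges] %in% keep_nodes &
                      edge_j[keep_edges] %in% keep_nodes]
  out <- g
  out$vectors <- g$vectors[keep_nodes, , drop = FALSE]
  out$mult <- g$mult[keep_nodes]
  out$median <- g$median[keep_nodes]
  out$labels <- g$labels[keep_nodes]
  out$edges <- g$edges[sel_e, , drop = FALSE]
  out$params$mp_mode <- mode
  # invariant: still connected over observed haplotypes
  ig <- mj_igraph(out)
  if (igraph::components(ig)$no > 1L) stop("MP pruning disconnected the network")
  out
}

#' Write a median-joining network as GraphML plus a flat edge list
#'
#' @param g an `mj_graph`.
#' @param prefix output prefix; writes `<prefix>.graphml` and
#'   `<prefix>_edges.tsv`.
#' @return The prefix, invisibly.
#' @export
write_mj_graph <- function(g, prefix) {
  ig <- mj_igraph(g)
  igraph::write_graph(ig, paste0(prefix, ".graphml"), format = "graphml")
  utils::write.table(g$edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
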