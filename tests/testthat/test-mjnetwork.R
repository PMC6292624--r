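test_that("frequency filter drops rare haplotypes and errors when nothing survives", {
  h <- haplotype_set(rbind(c(0, 0), c(1, 0), c(1, 1)), c(5L, 1L, 2L))
  f <- frequency_filter(h, 2L)
  expect_identical(f$mult, c(5L, 2L))
  expect_identical(nrow(f$vectors), 2L)
  expect_identical(frequency_filter(h, 1L)$mult, h$mult)  # identity
  singletons <- haplotype_set(rbind(c(0, 0), c(1, 1)), c(1L, 1L))
  expect_error(frequency_filter(singletons, 2L), "removed every haplotype")
})

test_that("star contraction collapses satellite clusters onto their centers", {
  # center (mult 10) with 3 satellites at distance 1, radius 1
  h <- haplotype_set(rbind(c(0, 0, 0, 0, 0),
                           c(1, 0, 0, 0, 0),
                           c(0, 1, 0, 0, 0),
                           c(0, 0, 1, 0, 0)), c(10L, 1L, 1L, 1L))
  sc <- star_contraction(h, 1L)
  expect_identical(nrow(sc$set$vectors), 1L)
  expect_identical(sc$set$mult, 13L)
  expect_identical(nrow(sc$log), 3L)
  expect_true(all(sc$log$center == "00000"))

  # two haplotypes at distance 5 with radius 1: unchanged
  far <- haplotype_set(rbind(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, 1)), c(2L, 3L))
  sc2 <- star_contraction(far, 1L)
  expect_identical(sc2$set$mult, far$mult)
  expect_identical(nrow(sc2$log), 0L)

  # single haplotype: unchanged
  one <- haplotype_set(matrix(c(0L, 1L), 1L), 4L)
  expect_identical(star_contraction(one, 5L)$set$mult, 4L)

  # total multiplicity is conserved by contraction
  set.seed(40)
  rnd <- collapse_haplotypes(matrix(rbinom(30 * 6, 1, 0.3), 30, 6))
  sc3 <- star_contraction(rnd, 2L)
  expect_identical(sum(sc3$set$mult), sum(rnd$mult))
})

test_that("median joining adds the Steiner node of a distance-2 triangle", {
  # two haplotypes differing at 2 positions: one edge labeled with both
  h2 <- haplotype_set(rbind(c(0, 0), c(1, 1)))
  g2 <- build_mj(h2, 0L)
  expect_identical(nrow(g2$vectors), 2L)
  expect_identical(nrow(g2$edges), 1L)
  expect_identical(g2$edges$positions, "1,2")

  # 110/101/011: the quasi-median 111 is the unique minimiser of total
  # connection length among all 2^3 candidate Steiner vectors
  tri <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  best <- sapply(0:7, function(x) {
    v <- as.integer(intToBits(x)[1:3])
    sum(apply(tri, 1L, function(r) sum(r != v)))
  })
  expect_identical(which(best == min(best)) - 1L, 7L)  # vector 111 uniquely
  g3 <- build_mj(haplotype_set(tri), 0L)
  expect_identical(sum(g3$median), 1L)
  expect_identical(unname(g3$vectors[g3$median, ]), c(1L, 1L, 1L))
  expect_identical(nrow(g3$edges), 3L)
  expect_true(all(g3$edges$weight == 1))

  # single haplotype: single node, no edges
  g1 <- build_mj(haplotype_set(matrix(c(0L, 1L, 0L), 1L)), 0L)
  expect_identical(nrow(g1$vectors), 1L)
  expect_identical(nrow(g1$edges), 0L)

  # inconsistent lengths are an input error
  expect_error(haplotype_set(rbind(c(0, 1), c(1, 2))), "0/1")
})

test_that("on ancestor-closed tree haplotypes the network equals the brute-force MST", {
  tr <- toy_tree(k = 2L)
  panel <- toy_panel(tr)
  hgs <- c("root", "R", "M", "H", "U", "H1", "U5a")
  vecs <- t(vapply(hgs, function(h) path_vector(tr, panel, h),
                   integer(nrow(panel))))
  h <- haplotype_set(vecs, rep(2L, length(hgs)), labels = hgs)
  g <- build_mj(h, 0L)
  expect_identical(sum(g$median), 0L)               # set is median-closed
  expect_identical(nrow(g$edges), length(hgs) - 1L) # a tree
  expect_equal(sum(g$edges$weight), oracle_mst_weight(vecs))
  # connectivity and presence of every observed haplotype
  expect_true(all(hgs %in% g$labels))
})

test_that("median nodes always lie in the brute-force quasi-median closure", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:6, 1L)
    L <- sample(4:10, 1L)
    vecs <- unique(matrix(rbinom(n * L, 1, 0.5), n, L))
    if (nrow(vecs) < 2L) next
    h <- haplotype_set(vecs)
    g <- build_mj(h, sample(0:2, 1L))
    if (!any(g$median)) next
    closure <- qm_closure(vecs)
    closure_keys <- apply(closure, 1L, paste, collapse = "")
    med_keys <- apply(g$vectors[g$median, , drop = FALSE], 1L,
                      paste, collapse = "")
    expect_true(all(med_keys %in% closure_keys))
    # every observed haplotype is a node and the graph is connected
    expect_true(all(h$labels %in% g$labels))
    ig <- igraph::graph_from_data_frame(g$edges[, 1:2], directed = FALSE,
                                        vertices = data.frame(name = g$labels))
    expect_equal(igraph::components(ig)$no, 1)
  }
})

test_that("rebuilding on a network's own node set adds no new medians", {
  set.seed(42)
  for (i in 1:10) {
    vecs <- unique(matrix(rbinom(5 * 8, 1, 0.5), 5, 8))
    if (nrow(vecs) < 3L) next
    g <- build_mj(haplotype_set(vecs), 0L)
    h2 <- haplotype_set(g$vectors, pmax(g$mult, 1L), labels = g$labels)
    g2 <- build_mj(h2, 0L)
    expect_identical(nrow(g2$vectors), nrow(g$vectors))
  }
})

test_that("MP post-processing keeps only medians on minimum-length connections", {
  # a tree-shaped network is its own unique spanning subgraph
  tri <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  g <- build_mj(haplotype_set(tri), 0L)
  mp <- mp_postprocess(g)
  expect_identical(mp$params$mp_mode, "exhaustive")
  expect_identical(nrow(mp$vectors), nrow(g$vectors))  # 111 stays
  expect_identical(nrow(mp$edges), nrow(g$edges))

  # chain of observed nodes with a median detour between b and d:
  # equal total length -> retained; strictly longer -> deleted
  obs4 <- rbind(a = c(0,1,1,0), b = c(1,1,0,0), c = c(0,0,1,1), d = c(1,0,0,1))
  mk_graph <- function(med_vec) {
    vecs <- rbind(obs4, m = med_vec)
    labels <- c("a", "b", "c", "d", "m")
    edges <- data.frame(
      from = c("a", "b", "d", "b", "m"),
      to   = c("b", "d", "c", "m", "d"),
      stringsAsFactors = FALSE)
    w <- vapply(seq_len(nrow(edges)), function(k) {
      i <- match(edges$from[k], labels); j <- match(edges$to[k], labels)
      sum(vecs[i, ] != vecs[j, ])
    }, 0)
    edges$weight <- w
    edges$positions <- ""
    structure(list(vectors = vecs, mult = c(1L, 1L, 1L, 1L, 0L),
                   median = c(rep(FALSE, 4L), TRUE),
                   labels = labels, edges = edges, params = list(epsilon = 0)),
              class = "mj_graph")
  }
  # b-m-d costs 1+1, tying the direct b-d edge of cost 2: both solutions are
  # minimum-length spanning subgraphs, so the median and the edge both stay
  g_eq <- mk_graph(c(1, 1, 0, 1))
  expect_identical(g_eq$edges$weight, c(2, 2, 2, 1, 1))
  mp_eq <- mp_postprocess(g_eq)
  expect_true("m" %in% mp_eq$labels)
  expect_true(any(mp_eq$edges$from == "b" & mp_eq$edges$to == "d"))
  # a 3+3 detour is strictly longer than the direct edge: median deleted
  g_long <- mk_graph(c(0, 1, 1, 1))
  expect_identical(g_long$edges$weight, c(2, 2, 2, 3, 3))
  mp_long <- mp_postprocess(g_long)
  expect_false("m" %in% mp_long$labels)
  expect_true(all(c("a", "b", "c", "d") %in% mp_long$labels))

  # heuristic mode engages above the exhaustive limit and stays connected
  set.seed(43)
  vecs <- unique(matrix(rbinom(10 * 12, 1, 0.5), 10, 12))
  gh <- build_mj(haplotype_set(vecs), 1L)
  mp_h <- mp_postprocess(gh, exhaustive_limit = 2L)
  expect_identical(mp_h$params$mp_mode, "heuristic")
  expect_true(all(apply(vecs, 1L, paste, collapse = "") %in%
                    apply(mp_h$vectors, 1L, paste, collapse = "")))
})

test_that("networks export to GraphML and an edge list", {
  tri <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1))
  g <- build_mj(haplotype_set(tri), 0L)
  prefix <- tempfile()
  write_mj_graph(g, prefix)
  expect_true(file.exists(paste0(prefix, ".graphml")))
  edges <- read.delim(paste0(prefix, "_edges.tsv"))
  expect_identical(nrow(edges), nrow(g$edges))
})

test_that("aligned SNP-string FASTA files load as binary haplotype sets", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACGT", ">s2", "ACGT", ">s3", "AGGT", ">s4", "ACGA"), fa)
  h <- haplotypes_from_fasta(fa)
  expect_identical(nrow(h$vectors), 3L)          # s1 == s2
  expect_identical(sum(h$mult), 4L)
  key <- apply(h$vectors, 1L, paste, collapse = "")
  expect_setequal(key, c("0000", "0100", "0001"))
  # three alleles in one column is an input error
  writeLines(c(">a", "A", ">b", "C", ">c", "G"), fa)
  expect_error(haplotypes_from_fasta(fa), "more than two alleles")
})
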