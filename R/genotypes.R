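#' Haploid genotype matrices
#'
#' Calls are stored as an integer matrix with samples in rows and loci in
#' columns: `0` = REF (ancestral array allele), `1` = ALT (derived), `NA` =
#' MISSING. Loci are keyed by 1-based rCRS position via the `loci` table.
#'
#' @param calls integer matrix (samples x loci) over {0, 1, NA}; rownames are
#'   sample ids.
#' @param loci data.frame with columns `id`, `position`, `ref`, `alt`; one row
#'   per matrix column, positions unique.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci) {
  stopifnot(is.matrix(calls), is.data.frame(loci),
            ncol(calls) == nrow(loci),
            all(c("id", "position", "ref", "alt") %in% names(loci)))
  if (anyDuplicated(loci$position)) stop("locus positions must be unique")
  storage.mode(calls) <- "integer"
  ok <- calls %in% c(0L, 1L, NA_integer_)
  if (!all(ok)) stop("calls must be 0 (REF), 1 (ALT) or NA (MISSING)")
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("S%05d", seq_len(nrow(calls)))
  }
  colnames(calls) <- loci$id
  structure(list(calls = calls, loci = loci), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cr <- mean(!is.na(x$calls))
  cat(sprintf("genotype_matrix: %d samples x %d loci, call rate %.1f%%\n",
              nrow(x$calls), nrow(x$loci), 100 * cr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Write a genotype matrix as PED/MAP (PLINK text dialect)
#'
#' MAP rows carry chromosome label "MT", the locus id, genetic distance 0 and
#' the 1-based rCRS position. The PED file encodes the haploid mtDNA call as a
#' homozygous diploid pair ("A A"), MISSING as "0 0".
#'
#' @param g a [genotype_matrix].
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return The prefix, invisibly.
#' @export
write_pedmap <- function(g, prefix) {
  map <- data.frame(chr = "MT", id = g$loci$id, cm = 0L,
                    pos = g$loci$position)
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele <- function(j) {
    a <- c(g$loci$ref[j], g$loci$alt[j])
    call <- g$calls[, j]
    out <- rep("0 0", length(call))
    out[!is.na(call)] <- paste(a[call[!is.na(call)] + 1L],
                               a[call[!is.na(call)] + 1L])
    out
  }
  geno <- vapply(seq_len(ncol(g$calls)), allele, character(nrow(g$calls)))
  if (nrow(g$calls) == 1L) geno <- matrix(geno, nrow = 1L)
  ped <- cbind(rownames(g$calls), rownames(g$calls), "0", "0", "0", "-9", geno)
  utils::write.table(ped, paste0(prefix, ".ped"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PED/MAP pair back into a genotype matrix
#'
#' @param prefix path prefix of the `.ped` / `.map` pair.
#' @return A [genotype_matrix]. The ref allele of each locus is taken from the
#'   supplied `panel` when given, otherwise the alphabetically first allele
#'   observed at the locus is treated as ref.
#' @param panel optional data.frame (`id`, `position`, `ref`, `alt`) fixing the
#'   allele orientation.
#' @export
read_pedmap <- function(prefix, panel = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(map) <- c("chr", "id", "cm", "pos")
  ped <- utils::read.table(paste0(prefix, ".ped"), sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  geno <- as.matrix(ped[, -(1:6), drop = FALSE])
  n_loci <- nrow(map)
  stopifnot(ncol(geno) == n_loci)
  if (is.null(panel)) {
    ref <- alt <- character(n_loci)
    for (j in seq_len(n_loci)) {
      al <- sort(unique(unlist(strsplit(geno[, j], " ", fixed = TRUE))))
      al <- setdiff(al, "0")
      ref[j] <- if (length(al) >= 1L) al[1L] else "A"
      alt[j] <- if (length(al) >= 2L) al[2L] else "G"
    }
    panel <- data.frame(id = map$id, position = map$pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  } else {
    panel <- panel[match(map$pos, panel$position), , drop = FALSE]
    if (anyNA(panel$position)) stop("panel does not cover every MAP position")
  }
  calls <- matrix(NA_integer_, nrow(geno), n_loci)
  for (j in seq_len(n_loci)) {
    first <- sub(" .*", "", geno[, j])
    calls[first == panel$ref[j], j] <- 0L
    calls[first == panel$alt[j], j] <- 1L
  }
  rownames(calls) <- ped[[2L]]
  genotype_matrix(calls, panel)
}

#' Read aligned SNP-string sequences from FASTA into a haplotype set
#'
#' Each record is one sample's concatenated SNP alleles (equal lengths). Per
#' column, the allele of the first sequence is taken as the 0 state unless a
#' reference allele string is supplied; any other allele is 1. More than two
#' alleles in a column is an input error.
#'
#' @param path FASTA file of aligned SNP strings.
#' @param ref optional reference allele string (length of the alignment).
#' @return A [haplotype_set] of the distinct sequences with multiplicities.
#' @export
haplotypes_from_fasta <- function(path, ref = NULL) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("reading FASTA input requires the seqinr package")
  }
  seqs <- seqinr::read.fasta(path, as.string = FALSE, forceDNAtolower = FALSE)
  if (!length(seqs)) stop("no sequences in ", path)
  mat <- toupper(do.call(rbind, lapply(seqs, as.character)))
  if (is.null(ref)) ref <- mat[1L, ] else {
    ref <- toupper(strsplit(ref, "")[[1L]])
    if (length(ref) != ncol(mat)) stop("ref length does not match alignment")
  }
  bin <- matrix(0L, nrow(mat), ncol(mat))
  for (j in seq_len(ncol(mat))) {
    al <- unique(mat[, j])
    if (length(setdiff(al, ref[j])) > 1L) {
      stop("column ", j, " has more than two alleles: ",
           paste(al, collapse = "/"))
    }
    bin[, j] <- as.integer(mat[, j] != ref[j])
  }
  collapse_haplotypes(bin)
}

#' Collapse a complete 0/1 matrix into distinct haplotypes
#'
#' @param m numeric/integer matrix over {0,1} with no missing values
#'   (rows = samples).
#' @return A [haplotype_set] of the distinct rows with multiplicities.
#' @export
collapse_haplotypes <- function(m) {
  if (anyNA(m)) stop("haplotype collapse requires complete calls")
  key <- apply(m, 1L, paste, collapse = "")
  tab <- table(key)
  keys <- names(tab)
  vecs <- t(vapply(strsplit(keys, ""), function(s) as.integer(s),
                   integer(ncol(m))))
  if (ncol(m) == 1L) vecs <- matrix(vecs, ncol = 1L)
  haplotype_set(vecs, as.integer(tab), labels = keys)
}
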