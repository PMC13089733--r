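## Haplotype and nucleotide diversity for a population alignment, following
## the conventions of classical population-genetics software (DnaSP):
## complete deletion of gapped/ambiguous columns by default, Nei's unbiased
## haplotype diversity with the n/(n-1) correction, S as the count of
## columns with >= 2 states, k as the mean pairwise Hamming distance and
## Pi = k / L. The per-site statistics are computed from column base
## frequencies (sum over sites of the number of differing pairs), which is
## algebraically identical to the pairwise double loop but O(nL).

#' Remove gapped or ambiguous alignment columns (complete deletion)
#'
#' @param aln a [Biostrings::DNAStringSet], character vector or character
#'   matrix (rows = sequences).
#' @return character matrix containing only columns free of \code{-} and
#'   \code{N}.
#' @export
completeDeletion <- function(aln) {
  m <- alignmentMatrix(aln)
  keep <- colSums(m == "-" | m == "N") == 0L
  if (!any(keep))
    stop("complete deletion removed every column")
  m[, keep, drop = FALSE]
}

## Pairwise deletion alternative: columns are kept, and pairwise distances
## ignore sites where either sequence is gapped/ambiguous. Used when
## filter = "pairwise".
pairwiseDeletionStats <- function(m) {
  n <- nrow(m)
  ok <- m != "-" & m != "N"
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- ok[i, ] & ok[j, ]
      total <- total + sum(m[i, use] != m[j, use])
    }
  }
  total / choose(n, 2)
}

#' Partition sequences into haplotype classes
#'
#' Groups exactly-identical rows of the (filtered) alignment.
#'
#' @param aln alignment (matrix, character vector or
#'   [Biostrings::DNAStringSet]); complete deletion should already have
#'   been applied if desired.
#' @return A list with \code{H} (number of haplotypes), \code{sizes}
#'   (integer class sizes, descending) and \code{classes} (list of row
#'   indices per haplotype).
#' @export
haplotypes <- function(aln) {
  m <- alignmentMatrix(aln)
  key <- apply(m, 1L, paste, collapse = "")
  classes <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  sizes <- sort(lengths(classes), decreasing = TRUE)
  list(H = length(classes), sizes = as.integer(unname(sizes)),
       classes = unname(classes))
}

#' Nei's unbiased haplotype diversity
#'
#' \deqn{H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with \eqn{p_i} the haplotype class frequencies: the probability that two
#' sequences drawn without replacement belong to different haplotypes.
#'
#' @param sizes integer vector of haplotype class sizes (or the list
#'   returned by [haplotypes()]).
#' @param n sample size; defaults to \code{sum(sizes)}.
#' @return haplotype diversity in \eqn{[0, 1]}.
#' @examples
#' haplotypeDiversity(c(2, 1, 1))  # n = 4: 0.8333...
#' @export
haplotypeDiversity <- function(sizes, n = NULL) {
  if (is.list(sizes)) sizes <- sizes$sizes
  sizes <- as.integer(sizes)
  if (is.null(n)) n <- sum(sizes)
  if (n < 2L) stop("haplotype diversity requires n >= 2")
  p <- sizes / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Segregating sites and pairwise nucleotide statistics
#'
#' Computes S (columns with at least two states), k (average pairwise
#' Hamming distance over all \eqn{C(n,2)} sequence pairs), Pi (= k / L)
#' and the mean pairwise p-distance (identical to Pi under these
#' definitions). The alignment must already be free of gaps/ambiguity
#' (apply [completeDeletion()] first).
#'
#' @param aln filtered alignment.
#' @return A list with \code{S}, \code{k}, \code{Pi}, \code{d_within},
#'   \code{n}, \code{L}.
#' @export
pairwiseStatistics <- function(aln) {
  m <- alignmentMatrix(aln)
  n <- nrow(m); L <- ncol(m)
  if (n < 2L) stop("pairwise statistics require n >= 2 sequences")
  npairs <- choose(n, 2)
  ## per-column state counts: pairs differing at a column =
  ## C(n,2) - sum_b C(n_b,2)
  diffs_per_col <- apply(m, 2L, function(col) {
    tab <- tabulate(factor(col, levels = unique(col)))
    npairs - sum(choose(tab, 2))
  })
  S <- sum(diffs_per_col > 0)
  k <- sum(diffs_per_col) / npairs
  Pi <- k / L
  list(S = as.integer(S), k = k, Pi = Pi, d_within = Pi, n = n, L = L)
}

#' All diversity indices for an alignment
#'
#' One-call wrapper: filters the alignment (complete deletion by default,
#' pairwise deletion on request), partitions haplotypes and computes
#' H, Hd, S, k, Pi and the within-group distance.
#'
#' @param aln a [Biostrings::DNAStringSet], character vector or matrix.
#' @param filter \code{"complete"} (default) or \code{"pairwise"} or
#'   \code{"none"}.
#' @return A [DiversityResult-class].
#' @examples
#' aln <- c(a = "AAAA", b = "AAAA", c = "AAAT")
#' diversityIndices(aln)
#' @export
diversityIndices <- function(aln, filter = c("complete", "pairwise", "none")) {
  filter <- match.arg(filter)
  m <- alignmentMatrix(aln)
  if (nrow(m) < 2L) stop("diversity indices require n >= 2 sequences")
  if (filter == "complete") m <- completeDeletion(m)
  hap <- haplotypes(m)
  if (filter == "pairwise") {
    ## haplotypes and S on the raw matrix; k by pairwise deletion
    clean <- m
    S <- sum(apply(m, 2L, function(col) {
      col <- col[col != "-" & col != "N"]
      length(unique(col)) >= 2L
    }))
    k <- pairwiseDeletionStats(m)
    L <- ncol(m)
    Pi <- k / L
    stats <- list(S = as.integer(S), k = k, Pi = Pi, d_within = Pi,
                  n = nrow(m), L = L)
  } else {
    stats <- pairwiseStatistics(m)
  }
  new("DiversityResult", n = as.integer(stats$n), L = as.integer(stats$L),
      H = as.integer(hap$H),
      Hd = if (hap$H == 1L) 0 else haplotypeDiversity(hap$sizes, stats$n),
      S = stats$S, k = stats$k, Pi = stats$Pi, d_within = stats$d_within,
      class_sizes = hap$sizes)
}
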