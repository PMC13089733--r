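## Nucleotide composition and strand-asymmetry statistics. The two skew
## statistics measure compositional bias between complementary bases on the
## reported strand:
##   AT-skew = (A - T) / (A + T)
##   GC-skew = (G - C) / (G + C)
## Both are scale-invariant, so counts and percentages give identical values.

#' Strand-asymmetry skew statistic
#'
#' \code{(x - y) / (x + y)}: the AT-skew with \code{x = A}, \code{y = T}
#' counts (or percentages), the GC-skew with \code{x = G}, \code{y = C}.
#' Dimensionless, bounded in \eqn{[-1, 1]}, scale-invariant and
#' antisymmetric. A zero denominator yields \code{NaN} (undefined), never 0.
#'
#' @param x,y non-negative counts or percentages (vectorized).
#' @return numeric skew values.
#' @examples
#' skew(34.1, 25.0)  # whole-mitogenome AT-skew from printed percentages
#' skew(9.1, 29.1)   # atp8 GC-skew
#' @export
skew <- function(x, y) {
  stopifnot(all(x >= 0, na.rm = TRUE), all(y >= 0, na.rm = TRUE))
  denom <- x + y
  out <- (x - y) / denom
  out[denom == 0] <- NaN
  out
}

#' Base composition of a DNA sequence
#'
#' Counts and percentages of A, C, G, T (computed over non-N bases; N is
#' tallied separately) plus A+T content and the AT-/GC-skews.
#'
#' @param seq a single DNA string or a [Biostrings::DNAString].
#' @return A list with \code{counts} (named integer, A/C/G/T), \code{n_N},
#'   \code{pct} (named numeric), \code{at_pct}, \code{at_skew},
#'   \code{gc_skew}, \code{length}.
#' @examples
#' baseComposition("AATT")$at_skew   # 0
#' @export
baseComposition <- function(seq) {
  chr <- normalizeDnaString(as.character(seq))
  if (nchar(chr) == 0L) stop("empty sequence")
  tab <- table(factor(strsplit(chr, "")[[1]], levels = c("A", "C", "G", "T", "N")))
  counts <- c(A = unname(tab["A"]), C = unname(tab["C"]),
              G = unname(tab["G"]), T = unname(tab["T"]))
  counts <- vapply(counts, as.integer, integer(1))
  n_N <- as.integer(tab["N"])
  tot <- sum(counts)
  if (tot == 0L) stop("sequence contains no unambiguous bases")
  if (n_N > 0.1 * (tot + n_N))
    warning("more than 10% ambiguous (N) bases")
  pct <- 100 * counts / tot
  list(counts = counts, n_N = n_N, pct = pct,
       at_pct = unname(pct["A"] + pct["T"]),
       at_skew = skew(counts[["A"]], counts[["T"]]),
       gc_skew = skew(counts[["G"]], counts[["C"]]),
       length = tot + n_N)
}

## Plus-strand slice of a feature's coordinate range, wrap-aware.
featureSlice <- function(seqchr, start, end, genome_length) {
  if (end >= start) return(substr(seqchr, start, end))
  paste0(substr(seqchr, start, genome_length), substr(seqchr, 1, end))
}

#' Per-feature composition table
#'
#' One composition row per annotated feature plus a whole-mitogenome row,
#' in the conventional column order (T%, C%, A%, G%, A+T%, AT-skew,
#' GC-skew). By default each feature's profile is computed on the genome
#' plus-strand slice of its coordinate range regardless of feature strand
#' (the convention of published mitogenome composition tables, under which
#' the sole minus-strand PCG shows sign-inverted skews); set
#' \code{coding_strand = TRUE} to reverse-complement minus-strand features
#' first.
#'
#' @param mg a sequence-bearing [Mitogenome-class].
#' @param coding_strand use each feature's coding strand instead of the
#'   genome plus strand.
#' @param digits_pct,digits_skew report precisions (defaults: 1 and 3
#'   decimals, the usual print precisions).
#' @return data.frame with columns \code{Gene}, \code{T_pct}, \code{C_pct},
#'   \code{A_pct}, \code{G_pct}, \code{AT_pct}, \code{AT_skew},
#'   \code{GC_skew}; the final row is the whole mitogenome.
#' @export
perFeatureComposition <- function(mg, coding_strand = FALSE,
                                  digits_pct = 1, digits_skew = 3) {
  seqchr <- mg@sequence
  if (length(seqchr) == 0L)
    stop("record carries no sequence; use a GenBank or FASTA-backed input")
  ft <- features(mg)
  slices <- vapply(seq_len(nrow(ft)), function(i)
    featureSlice(seqchr, ft$start[i], ft$end[i], genomeLength(mg)),
    character(1))
  if (coding_strand && any(ft$strand == "-")) {
    neg <- ft$strand == "-"
    slices[neg] <- revcompChr(slices[neg])
  }
  rows <- lapply(c(slices, seqchr), function(s) {
    p <- baseComposition(s)
    data.frame(T_pct = round(p$pct[["T"]], digits_pct),
               C_pct = round(p$pct[["C"]], digits_pct),
               A_pct = round(p$pct[["A"]], digits_pct),
               G_pct = round(p$pct[["G"]], digits_pct),
               AT_pct = round(p$at_pct, digits_pct),
               AT_skew = round(p$at_skew, digits_skew),
               GC_skew = round(p$gc_skew, digits_skew))
  })
  out <- do.call(rbind, rows)
  out <- cbind(Gene = c(ft$name, "mitogenome"), out)
  rownames(out) <- NULL
  out
}

#' Skews recomputed from printed composition percentages
#'
#' Applies the skew formulas to a table of printed base percentages (such
#' as [hatraCompositionTable()]), returning the recomputed skews next to
#' the printed ones. Because the inputs are rounded to one decimal, the
#' recomputed third decimal can differ slightly from skews computed on raw
#' counts.
#'
#' @param tab data.frame with columns \code{Gene}, \code{T_pct},
#'   \code{C_pct}, \code{A_pct}, \code{G_pct} and (optionally) printed
#'   \code{AT_skew}, \code{GC_skew}.
#' @return the input with added columns \code{AT_skew_calc},
#'   \code{GC_skew_calc}.
#' @export
skewFromPercentages <- function(tab) {
  stopifnot(all(c("A_pct", "T_pct", "G_pct", "C_pct") %in% names(tab)))
  tab$AT_skew_calc <- skew(tab$A_pct, tab$T_pct)
  tab$GC_skew_calc <- skew(tab$G_pct, tab$C_pct)
  tab
}
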