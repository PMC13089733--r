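## Feature geometry: lengths, intergenic spacers / overlaps with signed
## sizes, the four-way overlap typology, strand tallies and the linear gene
## order. The signed gap between consecutive features is
## start(next) - end(prev) - 1: positive = spacer, negative = overlap,
## 0 = abutting. The origin-spanning pair is excluded from the gap list and
## reported separately as the unannotated wraparound (putative control
## region).

OVERLAP_TYPES <- c("opposite_strand", "stop_codon", "pcg_pcg", "other")

#' Length of a feature in bp
#'
#' \code{end - start + 1} for ordinary features; origin-wrapping features
#' (\code{end < start}) are legal on circular genomes and have length
#' \code{(genome_length - start + 1) + end}.
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @param genome_length total genome length in bp.
#' @param circular logical; wrapping coordinates on a linear record are an
#'   error.
#' @return integer vector of lengths.
#' @examples
#' featureLength(6244, 8079, 15788)   # nad5: 1836
#' featureLength(15700, 50, 15788)    # wraps the origin: 139
#' @export
featureLength <- function(start, end, genome_length, circular = TRUE) {
  start <- as.integer(start); end <- as.integer(end)
  wraps <- end < start
  if (any(wraps) && !circular)
    stop("feature wraps the origin on a non-circular record")
  out <- integer(length(start))
  out[!wraps] <- end[!wraps] - start[!wraps] + 1L
  out[wraps] <- (as.integer(genome_length) - start[wraps] + 1L) + end[wraps]
  out
}

#' @rdname featureLength
#' @param mg a [Mitogenome-class]; \code{featureLengths()} returns the
#'   length of every feature in start order.
#' @export
featureLengths <- function(mg) {
  ft <- features(mg)
  featureLength(ft$start, ft$end, genomeLength(mg), isCircular(mg))
}

## Detect features fully contained in the previous feature (nested); these
## break the adjacent-pair gap model and are excluded from the length
## conservation identity.
nestedPairs <- function(mg) {
  ft <- features(mg)
  if (nrow(ft) < 2L) return(integer(0))
  which(ft$end[-1] <= cummax(ft$end[-nrow(ft)]) &
        ft$start[-1] >= 1L & ft$end[-1] >= ft$start[-1]) + 1L
}

#' Signed gaps between consecutive features
#'
#' For each consecutive pair of features (in start order) computes the
#' signed gap \code{start(next) - end(prev) - 1} and, for overlaps
#' (negative gaps), the overlap type. The origin-spanning pair (last
#' feature back to the first) is \emph{not} emitted here; its size appears
#' as \code{wraparound_unannotated} in [summarizeArchitecture()]. A feature
#' fully nested inside its predecessor is skipped with a warning: the
#' adjacent-pair gap is not defined for containment.
#'
#' @param mg a [Mitogenome-class].
#' @return data.frame with columns \code{upstream}, \code{upstream_start},
#'   \code{downstream}, \code{downstream_start}, \code{gap},
#'   \code{overlap_type} (NA for non-negative gaps).
#' @examples
#' gaps <- computeGaps(hatraGeneTable())
#' gaps[gaps$gap < 0, ]
#' @export
computeGaps <- function(mg) {
  ft <- features(mg)
  empty <- data.frame(upstream = character(0), upstream_start = integer(0),
                      downstream = character(0), downstream_start = integer(0),
                      gap = integer(0), overlap_type = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(ft) < 2L) return(empty)
  nested <- nestedPairs(mg)
  if (length(nested))
    warning("nested feature(s) skipped in gap analysis: ",
            paste(ft$name[nested], collapse = ", "))
  keep <- setdiff(seq_len(nrow(ft)), nested)
  ft <- ft[keep, , drop = FALSE]
  if (nrow(ft) < 2L) return(empty)
  i <- seq_len(nrow(ft) - 1L)
  out <- data.frame(
    upstream = ft$name[i], upstream_start = ft$start[i],
    downstream = ft$name[i + 1L], downstream_start = ft$start[i + 1L],
    gap = ft$start[i + 1L] - ft$end[i] - 1L,
    overlap_type = NA_character_,
    stringsAsFactors = FALSE
  )
  ov <- which(out$gap < 0L)
  for (j in ov)
    out$overlap_type[j] <- classifyOverlap(
      ft[j, ], ft[j + 1L, ], out$gap[j])
  out
}

#' Classify a gene overlap
#'
#' Applies the four-way typology in fixed priority order:
#' \enumerate{
#'   \item \code{opposite_strand} - the two features lie on different
#'     strands;
#'   \item \code{stop_codon} - the overlapped interval is entirely
#'     contained in the upstream PCG's (at most 3 bp) stop codon, the
#'     signature of TA(A)-termination sharing;
#'   \item \code{pcg_pcg} - both features are protein-coding;
#'   \item \code{other} - anything else.
#' }
#' The priority order matters because the categories overlap logically
#' (e.g., an opposite-strand overlap may also touch a stop codon).
#'
#' @param upstream,downstream single-row feature data.frames (as in
#'   [features()]).
#' @param gap the signed gap; must be negative.
#' @return one of \code{"opposite_strand"}, \code{"stop_codon"},
#'   \code{"pcg_pcg"}, \code{"other"}.
#' @export
classifyOverlap <- function(upstream, downstream, gap) {
  if (gap >= 0L) stop("classifyOverlap() requires a negative gap")
  if (upstream$strand != downstream$strand) return("opposite_strand")
  ov_len <- -gap
  if (upstream$kind == "PCG") {
    stop_len <- if (!is.na(upstream$stop_codon)) nchar(upstream$stop_codon)
      else 3L
    ## overlap occupies the last ov_len bases of the upstream feature;
    ## contained in the stop codon iff it is no longer than the stop itself
    if (ov_len <= stop_len) return("stop_codon")
  }
  if (upstream$kind == "PCG" && downstream$kind == "PCG") return("pcg_pcg")
  "other"
}

#' Summarize mitogenome architecture
#'
#' Counts spacers (positive gaps) and overlaps (negative gaps) between
#' consecutive features, reports the extreme spacer and overlap with their
#' flanking pairs, the unannotated origin-spanning stretch, and per-kind
#' strand tallies.
#'
#' @param mg a [Mitogenome-class].
#' @return A list with elements \code{n_spacers}, \code{n_overlaps},
#'   \code{max_spacer} (list: size, upstream, downstream),
#'   \code{max_overlap} (likewise, size in bp), \code{wraparound_unannotated},
#'   \code{strand_counts} (kind x strand table), \code{gaps} (the
#'   [computeGaps()] table) and \code{overlap_types} (named counts).
#' @examples
#' summarizeArchitecture(hatraGeneTable())[c("n_spacers", "n_overlaps")]
#' @export
summarizeArchitecture <- function(mg) {
  ft <- features(mg)
  gaps <- computeGaps(mg)
  pos <- gaps[gaps$gap > 0L, , drop = FALSE]
  neg <- gaps[gaps$gap < 0L, , drop = FALSE]
  pairInfo <- function(df, idx) {
    if (!nrow(df)) return(list(size = NA_integer_, upstream = NA_character_,
                               downstream = NA_character_))
    list(size = abs(df$gap[idx]), upstream = df$upstream[idx],
         downstream = df$downstream[idx])
  }
  wrap <- NA_integer_
  if (nrow(ft) >= 1L && isCircular(mg)) {
    last_end <- max(ft$end)
    first_start <- min(ft$start)
    wrap <- (genomeLength(mg) - last_end) + (first_start - 1L)
  }
  strand_counts <- if (nrow(ft))
    table(kind = factor(ft$kind, levels = FEATURE_KINDS),
          strand = factor(ft$strand, levels = c("+", "-")))
  else table(kind = factor(character(0), levels = FEATURE_KINDS),
             strand = factor(character(0), levels = c("+", "-")))
  list(
    n_spacers = nrow(pos),
    n_overlaps = nrow(neg),
    max_spacer = pairInfo(pos, if (nrow(pos)) which.max(pos$gap) else 0L),
    max_overlap = pairInfo(neg, if (nrow(neg)) which.min(neg$gap) else 0L),
    wraparound_unannotated = wrap,
    strand_counts = strand_counts,
    overlap_types = table(factor(neg$overlap_type, levels = OVERLAP_TYPES)),
    gaps = gaps
  )
}

#' Extract the gene order of a record
#'
#' The (name, strand) sequence of all features by ascending start
#' coordinate, as a [GeneOrder-class] for rearrangement comparison.
#'
#' @param mg a [Mitogenome-class].
#' @return A [GeneOrder-class].
#' @export
extractGeneOrder <- function(mg) {
  ft <- features(mg)
  GeneOrder(ft$name, ft$strand, label = recordId(mg),
            circular = isCircular(mg))
}

#' Architecture report as a writable table
#'
#' Flat TSV-ready rendering of [computeGaps()]: one row per adjacent pair
#' with the signed gap and (for overlaps) the type.
#'
#' @param mg a [Mitogenome-class].
#' @param path optional output TSV path; when given the table is written.
#' @return the data.frame, invisibly when \code{path} is given.
#' @export
architectureReport <- function(mg, path = NULL) {
  gaps <- computeGaps(mg)
  out <- data.frame(pair = paste(gaps$upstream, gaps$downstream, sep = "->"),
                    gap = gaps$gap,
                    overlap_type = ifelse(is.na(gaps$overlap_type), "",
                                          gaps$overlap_type),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
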