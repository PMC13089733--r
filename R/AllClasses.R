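#' @import methods
NULL

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "other")

#' Mitogenome: an annotated (circular) mitochondrial genome
#'
#' The central container of the package: a genome identifier, its total
#' length, circularity flag, an optional nucleotide sequence and an ordered
#' feature table. Coordinates are 1-based inclusive throughout; a feature
#' with \code{end < start} wraps the origin and is only legal on a circular
#' record. Feature names need not be unique (mitogenomes carry tRNA
#' paralogs); feature identity is the pair (name, start).
#'
#' @slot id character(1), accession or label.
#' @slot length integer(1), total genome length in bp.
#' @slot circular logical(1).
#' @slot sequence character; either \code{character(0)} (no sequence) or a
#'   single string over \code{A,C,G,T,N} of exactly \code{length} characters.
#' @slot features data.frame with columns \code{name}, \code{kind},
#'   \code{start}, \code{end}, \code{strand}, \code{anticodon},
#'   \code{start_codon}, \code{stop_codon}, sorted ascending by \code{start}.
#'
#' @seealso [Mitogenome()] for the user-facing constructor,
#'   [readGeneTable()], [readGenBank()].
#' @export
setClass("Mitogenome",
  representation(
    id = "character",
    length = "integer",
    circular = "logical",
    sequence = "character",
    features = "data.frame"
  ),
  prototype(
    id = NA_character_,
    length = 0L,
    circular = TRUE,
    sequence = character(0),
    features = data.frame()
  )
)

emptyFeatureTable <- function() {
  data.frame(
    name = character(0), kind = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    anticodon = character(0), start_codon = character(0),
    stop_codon = character(0),
    stringsAsFactors = FALSE
  )
}

setValidity("Mitogenome", function(object) {
  msgs <- character(0)
  if (length(object@id) != 1L) msgs <- c(msgs, "id must be length 1")
  if (length(object@length) != 1L || is.na(object@length) || object@length < 0L)
    msgs <- c(msgs, "length must be a single non-negative integer")
  if (length(object@circular) != 1L || is.na(object@circular))
    msgs <- c(msgs, "circular must be TRUE or FALSE")
  if (length(object@sequence) > 1L)
    msgs <- c(msgs, "sequence must be character(0) or a single string")
  if (length(object@sequence) == 1L) {
    if (nchar(object@sequence) != object@length)
      msgs <- c(msgs, sprintf(
        "sequence length (%d) differs from genome length (%d)",
        nchar(object@sequence), object@length))
    if (grepl("[^ACGTN]", object@sequence))
      msgs <- c(msgs, "sequence contains characters outside {A,C,G,T,N}")
  }
  ft <- object@features
  req <- c("name", "kind", "start", "end", "strand",
           "anticodon", "start_codon", "stop_codon")
  if (nrow(ft) > 0L || ncol(ft) > 0L) {
    miss <- setdiff(req, names(ft))
    if (length(miss))
      msgs <- c(msgs, paste("feature table lacks columns:",
                            paste(miss, collapse = ", ")))
  }
  if (nrow(ft) > 0L && all(req %in% names(ft))) {
    if (!all(ft$kind %in% FEATURE_KINDS))
      msgs <- c(msgs, "feature kind must be one of PCG, tRNA, rRNA, other")
    if (!all(ft$strand %in% c("+", "-")))
      msgs <- c(msgs, "feature strand must be '+' or '-'")
    if (any(ft$start < 1L) || any(ft$end < 1L))
      msgs <- c(msgs, "feature coordinates must be >= 1")
    if (any(ft$end > object@length) || any(ft$start > object@length))
      msgs <- c(msgs, "feature coordinates exceed genome length")
    if (is.unsorted(ft$start))
      msgs <- c(msgs, "features must be sorted ascending by start")
    wraps <- ft$end < ft$start
    if (any(wraps) && !object@circular)
      msgs <- c(msgs, "origin-wrapping feature on a non-circular record")
    bad_ac <- ft$kind == "tRNA" & !is.na(ft$anticodon) &
      nchar(ft$anticodon) != 3L
    if (any(bad_ac))
      msgs <- c(msgs, "tRNA anticodons must have length 3 when present")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a Mitogenome
#'
#' @param features data.frame with at least \code{name}, \code{start},
#'   \code{end}, \code{strand}; missing optional columns (\code{kind},
#'   \code{anticodon}, \code{start_codon}, \code{stop_codon}) are filled,
#'   with \code{kind} inferred from the gene-name prefix
#'   (\code{cox/nad/atp/cob} = PCG, \code{trn} = tRNA, \code{rrn} = rRNA,
#'   anything else = other).
#' @param length total genome length in bp; defaults to \code{max(end)}.
#' @param id record label.
#' @param circular logical, default \code{TRUE} (mitogenomes are circular).
#' @param sequence optional genome sequence (a single string, or a
#'   [Biostrings::DNAString]); normalized to uppercase, \code{U} mapped to
#'   \code{T}.
#' @return A [Mitogenome-class] object.
#' @examples
#' mg <- Mitogenome(data.frame(name = c("cox1", "trnR"),
#'                             start = c(1L, 1567L), end = c(1557L, 1635L),
#'                             strand = "+"), length = 15788L)
#' nFeatures(mg)
#' @export
Mitogenome <- function(features = emptyFeatureTable(), length = NULL,
                       id = "mitogenome", circular = TRUE, sequence = NULL) {
  ft <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(ft) > 0L) {
    for (col in c("name", "start", "end", "strand")) {
      if (!col %in% names(ft))
        stop("feature table lacks mandatory column '", col, "'")
    }
    ft$start <- as.integer(ft$start)
    ft$end <- as.integer(ft$end)
    ft$strand <- as.character(ft$strand)
    if (!"kind" %in% names(ft)) ft$kind <- inferFeatureKind(ft$name)
    for (col in c("anticodon", "start_codon", "stop_codon")) {
      if (!col %in% names(ft)) ft[[col]] <- NA_character_
      ft[[col]] <- as.character(ft[[col]])
    }
    ft <- ft[order(ft$start), , drop = FALSE]
    rownames(ft) <- NULL
    ft <- ft[c("name", "kind", "start", "end", "strand",
               "anticodon", "start_codon", "stop_codon")]
  } else {
    ft <- emptyFeatureTable()
  }
  seqchr <- character(0)
  if (!is.null(sequence)) {
    seqchr <- normalizeDnaString(as.character(sequence))
  }
  if (is.null(length)) {
    length <- if (length(seqchr) == 1L) nchar(seqchr)
      else if (nrow(ft)) max(ft$end) else 0L
  }
  new("Mitogenome", id = as.character(id), length = as.integer(length),
      circular = isTRUE(circular), sequence = seqchr, features = ft)
}

inferFeatureKind <- function(name) {
  lower <- tolower(name)
  kind <- rep("other", length(name))
  kind[grepl("^(cox|nad|atp|cob)", lower)] <- "PCG"
  kind[grepl("^trn", lower)] <- "tRNA"
  kind[grepl("^rrn", lower)] <- "rRNA"
  kind
}

normalizeDnaString <- function(x) {
  x <- toupper(x)
  if (grepl("U", x, fixed = TRUE)) {
    warning("'U' bases normalized to 'T'")
    x <- gsub("U", "T", x, fixed = TRUE)
  }
  bad <- gsub("[ACGTN]", "", x)
  if (nchar(bad) > 0L)
    stop("sequence contains unsupported characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
  x
}

#' @describeIn Mitogenome-class number of annotated features
#' @param object,x a \code{Mitogenome}
#' @export
nFeatures <- function(x) nrow(x@features)

#' Accessors for Mitogenome objects
#'
#' \code{features()} returns the ordered feature table; \code{genomeLength()}
#' the total length in bp; \code{genomeSequence()} the sequence as a
#' [Biostrings::DNAString] (or \code{NULL}); \code{isCircular()} and
#' \code{recordId()} the obvious scalars.
#'
#' @param x a [Mitogenome-class] object.
#' @return See description per accessor.
#' @name mitogenome-accessors
#' @export
features <- function(x) x@features

#' @rdname mitogenome-accessors
#' @export
genomeLength <- function(x) x@length

#' @rdname mitogenome-accessors
#' @export
genomeSequence <- function(x) {
  if (length(x@sequence) == 0L) return(NULL)
  Biostrings::DNAString(x@sequence)
}

#' @rdname mitogenome-accessors
#' @export
isCircular <- function(x) x@circular

#' @rdname mitogenome-accessors
#' @export
recordId <- function(x) x@id

setMethod("show", "Mitogenome", function(object) {
  cat(sprintf("Mitogenome '%s': %s bp, %s\n", object@id,
              format(object@length, big.mark = ","),
              if (object@circular) "circular" else "linear"))
  cat(sprintf("  sequence: %s\n",
              if (length(object@sequence)) "attached" else "absent"))
  ft <- object@features
  if (nrow(ft)) {
    tab <- table(factor(ft$kind, levels = FEATURE_KINDS))
    cat(sprintf("  %d features (%s)\n", nrow(ft),
                paste(sprintf("%d %s", tab, names(tab))[tab > 0],
                      collapse = ", ")))
  } else {
    cat("  no features\n")
  }
  invisible(NULL)
})

#' GeneOrder: a signed mitochondrial gene-order signature
#'
#' The (name, orientation) sequence of genes around a (usually circular)
#' mitogenome, used by the rearrangement-comparison functions.
#'
#' @slot label character(1) species / record id.
#' @slot order data.frame with columns \code{name} and \code{strand}.
#' @slot circular logical(1).
#' @seealso [extractGeneOrder()], [canonicalizeOrder()],
#'   [breakpointDistance()].
#' @export
setClass("GeneOrder",
  representation(label = "character", order = "data.frame",
                 circular = "logical"),
  prototype(label = NA_character_,
            order = data.frame(name = character(0), strand = character(0)),
            circular = TRUE)
)

setValidity("GeneOrder", function(object) {
  msgs <- character(0)
  if (!all(c("name", "strand") %in% names(object@order)) &&
      nrow(object@order) > 0L)
    msgs <- c(msgs, "order must have columns name, strand")
  if (nrow(object@order) && !all(object@order$strand %in% c("+", "-")))
    msgs <- c(msgs, "orientations must be '+' or '-'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneOrder
#'
#' @param name character vector of gene names.
#' @param strand character vector of orientations (\code{"+"}/\code{"-"}),
#'   recycled.
#' @param label record label.
#' @param circular logical.
#' @return A [GeneOrder-class] object.
#' @export
GeneOrder <- function(name, strand = "+", label = "order", circular = TRUE) {
  ord <- data.frame(name = as.character(name),
                    strand = rep_len(as.character(strand), length(name)),
                    stringsAsFactors = FALSE)
  new("GeneOrder", label = as.character(label), order = ord,
      circular = isTRUE(circular))
}

setMethod("show", "GeneOrder", function(object) {
  o <- object@order
  cat(sprintf("GeneOrder '%s' (%s, %d genes)\n", object@label,
              if (object@circular) "circular" else "linear", nrow(o)))
  if (nrow(o))
    cat(" ", paste0(ifelse(o$strand == "-", "-", ""), o$name,
                    collapse = " "), "\n")
  invisible(NULL)
})

#' @rdname GeneOrder-class
#' @param x a \code{GeneOrder}
#' @export
orderTable <- function(x) x@order

#' CodonUsage: codon counts, RSCU and amino-acid composition
#'
#' @slot table_id integer(1) NCBI translation-table id.
#' @slot counts named integer over sense codons.
#' @slot rscu named numeric: relative synonymous codon usage per codon.
#' @slot aa_counts named integer per amino acid.
#' @slot aa_pct named numeric, percentages summing to 100.
#' @slot n_codons_used integer(1): sense codons observed at least once.
#' @slot n_ambiguous integer(1): N-containing codons skipped.
#' @slot audit data.frame: per-PCG start/stop codon audit.
#' @seealso [codonReport()], [rscu()], [aminoAcidComposition()].
#' @export
setClass("CodonUsage",
  representation(table_id = "integer", counts = "integer", rscu = "numeric",
                 aa_counts = "integer", aa_pct = "numeric",
                 n_codons_used = "integer", n_ambiguous = "integer",
                 audit = "data.frame"))

setMethod("show", "CodonUsage", function(object) {
  cat(sprintf("CodonUsage (translation table %d)\n", object@table_id))
  cat(sprintf("  %d codons counted across %d PCGs; %d of %d sense codons used\n",
              sum(object@counts), nrow(object@audit), object@n_codons_used,
              length(object@counts)))
  top <- sort(object@rscu[!is.na(object@rscu)], decreasing = TRUE)
  if (length(top)) {
    cat("  top RSCU:", paste(sprintf("%s=%.2f", names(head(top, 3)),
                                     head(top, 3)), collapse = ", "), "\n")
    cat("  bottom RSCU:", paste(sprintf("%s=%.2f", names(tail(top, 3)),
                                        tail(top, 3)), collapse = ", "), "\n")
  }
  aa <- sort(object@aa_pct, decreasing = TRUE)
  cat(sprintf("  most used amino acid: %s (%.2f%%), least: %s (%.2f%%)\n",
              names(aa)[1], aa[1], names(aa)[length(aa)], aa[length(aa)]))
  invisible(NULL)
})

#' DiversityResult: haplotype and nucleotide diversity indices
#'
#' @slot n integer(1) sample size.
#' @slot L integer(1) analyzed sites after filtering.
#' @slot H integer(1) number of haplotypes.
#' @slot Hd numeric(1) haplotype diversity (Nei's unbiased estimator).
#' @slot S integer(1) segregating (polymorphic) sites.
#' @slot k numeric(1) average pairwise nucleotide differences.
#' @slot Pi numeric(1) nucleotide diversity per site (= k / L).
#' @slot d_within numeric(1) mean pairwise p-distance (= Pi under the
#'   implemented definitions).
#' @slot class_sizes integer vector of haplotype class sizes (descending).
#' @seealso [diversityIndices()].
#' @export
setClass("DiversityResult",
  representation(n = "integer", L = "integer", H = "integer", Hd = "numeric",
                 S = "integer", k = "numeric", Pi = "numeric",
                 d_within = "numeric", class_sizes = "integer"))

setMethod("show", "DiversityResult", function(object) {
  cat("Diversity indices\n")
  cat(sprintf("  n = %d sequences, L = %d sites\n", object@n, object@L))
  cat(sprintf("  H = %d haplotypes (sizes %s), Hd = %.3f\n", object@H,
              paste(object@class_sizes, collapse = ","), object@Hd))
  cat(sprintf("  S = %d, k = %.3f, Pi = %.4f, within-group distance = %.3f\n",
              object@S, object@k, object@Pi, object@d_within))
  invisible(NULL)
})

#' Tabulate a DiversityResult
#'
#' One-row data.frame shaped like a population-genetics summary table
#' (sample size, H, Hd, S, k, Pi, within-group distance), at the
#' conventional report precisions (Hd and k to 3 decimals, Pi to 4).
#'
#' @param x a [DiversityResult-class].
#' @param label optional row label (e.g., the gene fragment analyzed).
#' @return data.frame with one row.
#' @export
diversityTable <- function(x, label = "alignment") {
  data.frame(fragment = label, n = x@n, L = x@L, H = x@H,
             Hd = round(x@Hd, 3), S = x@S, k = round(x@k, 3),
             Pi = round(x@Pi, 4), d_within = round(x@d_within, 3),
             stringsAsFactors = FALSE)
}
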