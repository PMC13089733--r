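## Codon extraction from annotated PCGs, codon counting, RSCU and
## amino-acid composition under mitochondrial genetic codes. The default is
## NCBI translation table 9 (echinoderm/flatworm mitochondrial), which
## differs from the standard code in: AAA = Asn (not Lys), AGA/AGG = Ser
## (not Arg), TGA = Trp (not stop). Stops under table 9 are exactly
## TAA/TAG, and ATA stays Ile (unlike tables 2 and 5).

BASES <- c("T", "C", "A", "G")
## canonical codon order: first base outermost, third base fastest
ALL_CODONS <- apply(expand.grid(b3 = BASES, b2 = BASES, b1 = BASES)[, 3:1],
                    1L, paste0, collapse = "")

## Standard code (table 1), first base T,C,A,G outermost, then second, third.
STANDARD_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]

CODE_DIFFS <- list(
  `1` = c(),
  `2` = c(AGA = "*", AGG = "*", ATA = "M", TGA = "W"),
  `5` = c(AGA = "S", AGG = "S", ATA = "M", TGA = "W"),
  `9` = c(AAA = "N", AGA = "S", AGG = "S", TGA = "W")
)
START_CODONS <- list(
  `1` = c("TTG", "CTG", "ATG"),
  `2` = c("ATT", "ATC", "ATA", "ATG", "GTG"),
  `5` = c("TTG", "ATT", "ATC", "ATA", "ATG", "GTG"),
  `9` = c("ATG", "GTG")
)

#' Load a mitochondrial (or standard) genetic code
#'
#' Returns the full 64-codon map for NCBI translation table 1 (standard),
#' 2 (vertebrate mitochondrial), 5 (invertebrate mitochondrial) or 9
#' (echinoderm/flatworm mitochondrial, the default throughout this
#' package). The maps are defined as the standard code plus the documented
#' per-table substitutions.
#'
#' @param table_id one of 1, 2, 5, 9.
#' @return A list with \code{table_id}, \code{codon_map} (named character,
#'   64 codons to one-letter amino acid or \code{"*"}), \code{start_codons},
#'   \code{stop_codons}, \code{sense_codons} and \code{family} (amino acid
#'   to its synonymous sense codons).
#' @examples
#' code9 <- geneticCode(9)
#' code9$codon_map[c("AGA", "TGA", "AAA", "ATA")]
#' @export
geneticCode <- function(table_id = 9L) {
  key <- as.character(as.integer(table_id))
  if (!key %in% names(CODE_DIFFS))
    stop("unsupported translation table: ", table_id,
         " (supported: 1, 2, 5, 9)")
  map <- STANDARD_AA
  names(map) <- ALL_CODONS
  diffs <- CODE_DIFFS[[key]]
  map[names(diffs)] <- diffs
  sense <- names(map)[map != "*"]
  list(
    table_id = as.integer(table_id),
    codon_map = map,
    start_codons = START_CODONS[[key]],
    stop_codons = names(map)[map == "*"],
    sense_codons = sense,
    family = split(sense, map[sense])
  )
}

#' Reverse complement of DNA strings (plain character)
#'
#' @param x character vector of DNA strings over A,C,G,T,N.
#' @return character vector of reverse complements.
#' @export
revcompChr <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(s)), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract codons from an annotated PCG
#'
#' Takes the coding-strand sequence of a protein-coding feature (the
#' reverse complement of the genome slice for minus-strand genes), splits
#' it into triplets from the first position, and audits the first codon
#' against the code's start codons and the terminus against its stops. A
#' trailing 1-2 bp remainder is returned as an incomplete stop fragment
#' (completed to TAA by polyadenylation in vivo), not as a codon. Internal
#' stop codons raise a warning listing their codon positions.
#'
#' @param mg a sequence-bearing [Mitogenome-class].
#' @param feature a feature name, or a (name, start) pair as
#'   \code{c("atp6", 2845)} to disambiguate paralogs; alternatively a
#'   single-row data.frame from [features()].
#' @param code a genetic code from [geneticCode()].
#' @return A list with \code{codons} (ordered character vector),
#'   \code{remainder} (\code{""} or the 1-2 bp fragment), \code{start_ok},
#'   \code{stop_ok}, \code{stop_observed} and \code{internal_stops}
#'   (integer codon positions).
#' @export
extractCodons <- function(mg, feature, code = geneticCode(9)) {
  if (length(mg@sequence) == 0L)
    stop("record carries no sequence")
  row <- resolveFeature(mg, feature)
  if (row$kind != "PCG")
    stop("codon extraction requires a PCG feature; '", row$name,
         "' is ", row$kind)
  len <- featureLength(row$start, row$end, genomeLength(mg), isCircular(mg))
  if (len < 6L) stop("feature too short for codon extraction (", len, " bp)")
  cds <- featureSlice(mg@sequence, row$start, row$end, genomeLength(mg))
  if (row$strand == "-") cds <- revcompChr(cds)
  n_complete <- len %/% 3L
  starts <- seq(1L, by = 3L, length.out = n_complete)
  codons <- substring(cds, starts, starts + 2L)
  remainder <- if (len %% 3L) substr(cds, n_complete * 3L + 1L, len) else ""
  is_stop <- codons %in% code$stop_codons
  internal <- which(is_stop[-n_complete])
  if (length(internal))
    warning(sprintf("internal stop codon(s) in '%s' at codon position(s) %s",
                    row$name, paste(internal, collapse = ", ")))
  stop_observed <- if (nzchar(remainder)) remainder else codons[n_complete]
  stop_ok <- if (nzchar(remainder)) remainder %in% c("T", "TA")
    else codons[n_complete] %in% code$stop_codons
  list(codons = codons, remainder = remainder,
       start_ok = codons[1] %in% code$start_codons,
       stop_ok = stop_ok, stop_observed = stop_observed,
       internal_stops = internal)
}

resolveFeature <- function(mg, feature) {
  ft <- features(mg)
  if (is.data.frame(feature)) {
    stopifnot(nrow(feature) == 1L)
    return(feature)
  }
  if (length(feature) == 2L && !is.na(suppressWarnings(as.integer(feature[2])))) {
    hit <- ft[ft$name == feature[1] & ft$start == as.integer(feature[2]), ,
              drop = FALSE]
  } else {
    hit <- ft[ft$name == feature[1], , drop = FALSE]
  }
  if (nrow(hit) == 0L) stop("no such feature: ", paste(feature, collapse = "/"))
  if (nrow(hit) > 1L)
    stop("feature name '", feature[1], "' is ambiguous; address it as ",
         "c(name, start)")
  hit
}

#' Relative synonymous codon usage
#'
#' For codon \eqn{c} with amino acid \eqn{a} whose synonymous family has
#' \eqn{n_a} members, \eqn{RSCU(c) = count(c) / (\bar{count}_a)}: the
#' observed count divided by the mean count over the family. Uniform usage
#' within a family gives 1 for every member, and the family RSCU values
#' always sum to the family size. Families never observed get \code{NA}.
#' Stop codons are not part of any family.
#'
#' @param counts named integer vector of codon counts (sense codons;
#'   missing codons count 0).
#' @param code a genetic code from [geneticCode()].
#' @return named numeric over all sense codons of the code.
#' @examples
#' rscu(c(TTT = 3, TTC = 1), geneticCode(9))[c("TTT", "TTC")]  # 1.5, 0.5
#' @export
rscu <- function(counts, code = geneticCode(9)) {
  full <- stats::setNames(integer(length(code$sense_codons)),
                          code$sense_codons)
  counts <- counts[names(counts) %in% names(full)]
  full[names(counts)] <- as.integer(counts)
  out <- stats::setNames(rep(NA_real_, length(full)), names(full))
  for (fam in code$family) {
    total <- sum(full[fam])
    if (total > 0L) out[fam] <- full[fam] * length(fam) / total
  }
  out
}

#' Amino-acid composition from codon counts
#'
#' Percentage of each amino acid among all translated sense codons,
#' pooled over whatever genes produced \code{counts} (stop codons never
#' enter the counts).
#'
#' @inheritParams rscu
#' @return named numeric percentages summing to 100.
#' @export
aminoAcidComposition <- function(counts, code = geneticCode(9)) {
  if (!length(counts) || sum(counts) == 0L) stop("no codon counts")
  aa <- code$codon_map[names(counts)]
  if (anyNA(aa)) stop("counts contain unknown codons: ",
                      paste(names(counts)[is.na(aa)], collapse = ", "))
  if (any(aa == "*")) stop("counts must not include stop codons")
  tot <- tapply(as.integer(counts), aa, sum)
  stats::setNames(as.numeric(100 * tot / sum(tot)), names(tot))
}

#' Full codon-usage report for a record
#'
#' Aggregates all protein-coding genes on their coding strands: codon
#' counts (terminal complete stops excluded, incomplete terminal fragments
#' excluded and logged in the audit; N-containing codons skipped with a
#' tally), RSCU, amino-acid counts and percentages, and a per-gene
#' start/stop audit.
#'
#' @param mg a sequence-bearing [Mitogenome-class] with at least one PCG.
#' @param code a genetic code from [geneticCode()].
#' @return A [CodonUsage-class] object.
#' @export
codonReport <- function(mg, code = geneticCode(9)) {
  ft <- features(mg)
  pcgs <- ft[ft$kind == "PCG", , drop = FALSE]
  if (!nrow(pcgs)) stop("record has no protein-coding genes")
  counts <- stats::setNames(integer(length(code$sense_codons)),
                            code$sense_codons)
  n_ambiguous <- 0L
  audit <- list()
  for (i in seq_len(nrow(pcgs))) {
    ex <- extractCodons(mg, pcgs[i, , drop = FALSE], code)
    codons <- ex$codons
    ## drop the terminal complete stop from usage counts
    n <- length(codons)
    if (!nzchar(ex$remainder) && codons[n] %in% code$stop_codons)
      codons <- codons[-n]
    ambiguous <- grepl("N", codons, fixed = TRUE)
    n_ambiguous <- n_ambiguous + sum(ambiguous)
    codons <- codons[!ambiguous]
    ## any residual internal stops are excluded from sense counts
    codons <- codons[codons %in% code$sense_codons]
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
    audit[[i]] <- data.frame(
      gene = pcgs$name[i], start = pcgs$start[i],
      start_codon = ex$codons[1],
      stop_observed = if (nzchar(ex$remainder))
        paste0(ex$stop_observed, strrep("-", 3L - nchar(ex$remainder)))
      else ex$stop_observed,
      incomplete_stop = nzchar(ex$remainder),
      start_ok = ex$start_ok, stop_ok = ex$stop_ok,
      n_internal_stops = length(ex$internal_stops),
      stringsAsFactors = FALSE)
  }
  aa_pct <- aminoAcidComposition(counts[counts > 0L], code)
  aa_counts <- tapply(as.integer(counts), code$codon_map[names(counts)], sum)
  aa_counts <- aa_counts[names(aa_pct)]
  new("CodonUsage", table_id = code$table_id, counts = counts,
      rscu = rscu(counts, code),
      aa_counts = stats::setNames(as.integer(aa_counts), names(aa_pct)),
      aa_pct = aa_pct, n_codons_used = sum(counts > 0L),
      n_ambiguous = n_ambiguous,
      audit = do.call(rbind, audit))
}

#' Codon-usage table as a data.frame
#'
#' @param cu a [CodonUsage-class] from [codonReport()].
#' @return data.frame with columns \code{codon}, \code{aa}, \code{count},
#'   \code{RSCU}, sorted by amino acid then codon.
#' @export
codonTable <- function(cu) {
  code <- geneticCode(cu@table_id)
  out <- data.frame(codon = names(cu@counts),
                    aa = unname(code$codon_map[names(cu@counts)]),
                    count = unname(cu@counts),
                    RSCU = unname(cu@rscu),
                    stringsAsFactors = FALSE)
  out[order(out$aa, out$codon), ]
}
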