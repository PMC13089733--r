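## Readers and writers for the formats the pipeline touches: the
## gene-feature TSV (mirroring published annotation tables), GenBank flat
## files, and FASTA alignments. Coordinates are 1-based inclusive in every
## file; internal half-open conversions never reach disk.

GENE_TABLE_COLUMNS <- c("Gene", "Start", "End", "Strand", "Length",
                        "StartCodon", "StopCodon", "Anticodon")

#' Read a gene-feature table (TSV)
#'
#' Parses a tab-separated annotation table with mandatory columns
#' \code{Gene}, \code{Start}, \code{End}, \code{Strand} and optional
#' \code{Length}, \code{StartCodon}, \code{StopCodon}, \code{Anticodon}.
#' A pragma line \code{#length=<bp>} before the header sets the genome
#' length; without it the length defaults to \code{max(End)}. When a
#' \code{Length} column is present each printed value is checked against
#' \code{End - Start + 1} (wrap-aware) and mismatches raise a warning, not
#' an error. A tRNA whose anticodon decodes (under the echinoderm
#' mitochondrial code) to an amino acid other than the one in its name is
#' also flagged with a warning, since published tables occasionally carry
#' such inconsistencies.
#'
#' @param path file path.
#' @param id record label; defaults to the file base name.
#' @param circular logical, default \code{TRUE}.
#' @return A [Mitogenome-class] (without sequence).
#' @examples
#' tsv <- system.file("extdata", "hatra_gene_table.tsv", package = "mitochar")
#' mg <- suppressWarnings(readGeneTable(tsv))
#' nFeatures(mg)
#' @export
readGeneTable <- function(path, id = NULL, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pragma_len <- NA_integer_
  pragmas <- grep("^#", lines)
  for (i in pragmas) {
    m <- regmatches(lines[i], regexec("^#\\s*length\\s*=\\s*([0-9]+)", lines[i]))[[1]]
    if (length(m) == 2L) pragma_len <- as.integer(m[2])
  }
  body <- if (length(pragmas)) lines[-pragmas] else lines
  if (!length(body)) stop("gene table '", path, "' has no header line")
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  mandatory <- c("Gene", "Start", "End", "Strand")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss))
    stop("gene table lacks mandatory column(s): ", paste(miss, collapse = ", "))
  for (col in c("Start", "End")) {
    v <- trimws(tab[[col]])
    if (any(!grepl("^[0-9]+$", v)))
      stop("non-integer coordinate in column ", col)
    tab[[col]] <- as.integer(v)
  }
  blank2na <- function(x) { x <- trimws(x); x[!nzchar(x)] <- NA_character_; x }
  ft <- data.frame(
    name = trimws(tab$Gene),
    start = tab$Start, end = tab$End, strand = trimws(tab$Strand),
    stringsAsFactors = FALSE
  )
  optcol <- function(col) {
    if (col %in% names(tab)) blank2na(tab[[col]])
    else rep(NA_character_, nrow(tab))
  }
  ft$anticodon <- optcol("Anticodon")
  ft$start_codon <- optcol("StartCodon")
  ft$stop_codon <- optcol("StopCodon")
  len <- if (!is.na(pragma_len)) pragma_len else max(ft$end, 1L)
  if (!circular && any(ft$end < ft$start))
    stop("start > end on a non-circular record")
  mg <- Mitogenome(ft, length = len,
                   id = if (is.null(id)) tools::file_path_sans_ext(basename(path)) else id,
                   circular = circular)
  if ("Length" %in% names(tab)) {
    printed <- suppressWarnings(as.integer(trimws(tab$Length)))
    ord <- order(ft$start)
    computed <- vapply(ord, function(i)
      featureLength(ft$start[i], ft$end[i], len, circular), integer(1))
    printed <- printed[ord]
    bad <- which(!is.na(printed) & printed != computed)
    if (length(bad))
      warning("printed Length disagrees with End-Start+1 for: ",
              paste(sprintf("%s (%d vs %d)", ft$name[ord][bad],
                            printed[bad], computed[bad]), collapse = ", "))
  }
  auditAnticodons(mg)
  mg
}

## One-letter-ish gene-name suffix -> expected amino acid for tRNAs.
TRNA_AA <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
             Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
             L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
             S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")
AA3 <- c("A" = "Ala", "R" = "Arg", "N" = "Asn", "D" = "Asp", "C" = "Cys",
         "Q" = "Gln", "E" = "Glu", "G" = "Gly", "H" = "His", "I" = "Ile",
         "L" = "Leu", "K" = "Lys", "M" = "Met", "F" = "Phe", "P" = "Pro",
         "S" = "Ser", "T" = "Thr", "W" = "Trp", "Y" = "Tyr", "V" = "Val")

anticodonToAA <- function(anticodon, code = geneticCode(9)) {
  ac <- gsub("U", "T", toupper(anticodon), fixed = TRUE)
  if (is.na(ac) || nchar(ac) != 3L || grepl("[^ACGT]", ac)) return(NA_character_)
  codon <- revcompChr(ac)
  aa <- unname(code$codon_map[codon])
  if (is.na(aa) || aa == "*") NA_character_ else unname(AA3[aa])
}

auditAnticodons <- function(mg) {
  ft <- features(mg)
  trna <- ft[ft$kind == "tRNA" & !is.na(ft$anticodon), , drop = FALSE]
  for (i in seq_len(nrow(trna))) {
    letter <- toupper(substr(sub("^trn", "", trna$name[i]), 1, 1))
    expected <- unname(TRNA_AA[letter])
    if (is.na(expected)) next
    decoded <- anticodonToAA(trna$anticodon[i])
    if (!is.na(decoded) && decoded != expected)
      warning(sprintf(
        "tRNA '%s' (start %d): anticodon %s decodes to %s, not %s",
        trna$name[i], trna$start[i], trna$anticodon[i], decoded, expected))
  }
  invisible(mg)
}

#' Write a gene-feature table (TSV)
#'
#' Inverse of [readGeneTable()]: emits the \code{#length=} pragma, the full
#' column set and one row per feature in start order. Optional fields are
#' written as empty strings. Output is canonical, so write-read-write is
#' byte-stable.
#'
#' @param mg a [Mitogenome-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneTable <- function(mg, path) {
  ft <- features(mg)
  na2blank <- function(x) ifelse(is.na(x), "", x)
  rows <- if (nrow(ft)) {
    lens <- vapply(seq_len(nrow(ft)), function(i)
      featureLength(ft$start[i], ft$end[i], genomeLength(mg), isCircular(mg)),
      integer(1))
    paste(ft$name, ft$start, ft$end, ft$strand, lens,
          na2blank(ft$start_codon), na2blank(ft$stop_codon),
          na2blank(ft$anticodon), sep = "\t")
  } else character(0)
  writeLines(c(sprintf("#length=%d", genomeLength(mg)),
               paste(GENE_TABLE_COLUMNS, collapse = "\t"), rows), path)
  invisible(path)
}

#' Load the packaged H. atra annotation fixture
#'
#' The published annotation table of the Holothuria atra mitogenome
#' (GenBank PV998923): 37 features (13 PCGs, 22 tRNAs, 2 rRNAs) on a
#' 15,788 bp circular genome. The table is preserved exactly as printed,
#' including its known anticodon inconsistency for the feature labelled
#' \code{trnL} at 13,133 bp (anticodon GAU, an isoleucine anticodon), which
#' is surfaced as a warning unless \code{quiet = TRUE}.
#'
#' @param quiet suppress the annotation-audit warnings.
#' @return A [Mitogenome-class] without sequence.
#' @export
hatraGeneTable <- function(quiet = TRUE) {
  tsv <- system.file("extdata", "hatra_gene_table.tsv", package = "mitochar",
                     mustWork = TRUE)
  if (quiet) suppressWarnings(readGeneTable(tsv, id = "PV998923"))
  else readGeneTable(tsv, id = "PV998923")
}

#' Load the packaged H. atra composition table fixture
#'
#' The published per-gene nucleotide composition (percentages of T, C, A, G,
#' A+T content) and printed AT-/GC-skews of the H. atra mitogenome, one row
#' per gene plus a whole-mitogenome row. Used to cross-check the skew
#' formulas against printed values.
#'
#' @return data.frame with columns Gene, T_pct, C_pct, A_pct, G_pct,
#'   AT_pct, AT_skew, GC_skew.
#' @export
hatraCompositionTable <- function() {
  tsv <- system.file("extdata", "hatra_composition_table.tsv",
                     package = "mitochar", mustWork = TRUE)
  utils::read.delim(tsv, stringsAsFactors = FALSE)
}

## ---- GenBank flat files ---------------------------------------------------
## Minimal flat-file parser/writer covering what annotated mitogenomes need:
## LOCUS, FEATURES (gene/CDS/tRNA/rRNA, complement(), origin-spanning join()),
## ORIGIN. No installed R package reads GenBank *files* (as opposed to
## fetching from NCBI), so this is implemented here.

#' Read a GenBank flat file
#'
#' Parses LOCUS, the FEATURES table (CDS, tRNA, rRNA and misc features;
#' \code{complement(...)} marks the minus strand; a two-segment
#' \code{join(a..L,1..b)} spanning the origin is accepted on circular
#' records) and the ORIGIN sequence. \code{/gene}, \code{/anticodon} and
#' \code{/transl_table} qualifiers are honoured.
#'
#' @param path file path.
#' @return A [Mitogenome-class] with sequence attached.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("not a GenBank flat file: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  declared_len <- as.integer(locus[3])
  circular <- any(grepl("circular", lines[locus_i[1]], ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  if (!length(feat_i)) stop("GenBank file has no FEATURES table")
  origin_i <- grep("^ORIGIN", lines)
  feat_end <- if (length(origin_i)) origin_i[1] - 1L else length(lines)
  fl <- lines[(feat_i[1] + 1L):feat_end]

  ## split the features block into (key, location, qualifiers) entries
  is_key <- grepl("^ {5}\\S", fl)
  idx <- cumsum(is_key)
  entries <- split(fl[idx > 0], idx[idx > 0])
  feats <- list()
  for (e in entries) {
    header <- strsplit(trimws(e[1]), "\\s+")[[1]]
    key <- header[1]
    if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop"))
      next
    ## location may continue over lines until the first /qualifier
    rest <- e[-1]
    qual_start <- which(grepl("^\\s*/", rest))[1]
    loc_lines <- if (is.na(qual_start)) rest else rest[seq_len(qual_start - 1L)]
    loc <- paste0(header[2], paste(trimws(loc_lines), collapse = ""))
    quals <- if (is.na(qual_start)) character(0) else trimws(rest[qual_start:length(rest)])
    parsed <- parseGenBankLocation(loc, circular)
    getq <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (!length(hit)) return(NA_character_)
      gsub('^"|"$', "", sub(paste0("^/", name, "="), "", hit[1]))
    }
    gene <- getq("gene")
    if (is.na(gene)) gene <- getq("product")
    if (is.na(gene)) gene <- tolower(key)
    kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "other")
    ac <- getq("anticodon")
    if (!is.na(ac) && grepl("seq:", ac))
      ac <- toupper(sub(".*seq:([A-Za-z]{3}).*", "\\1", ac))
    feats[[length(feats) + 1L]] <- data.frame(
      name = gene, kind = kind, start = parsed$start, end = parsed$end,
      strand = parsed$strand,
      anticodon = if (is.na(ac)) NA_character_ else toupper(ac),
      start_codon = NA_character_, stop_codon = NA_character_,
      stringsAsFactors = FALSE)
  }
  ft <- if (length(feats)) do.call(rbind, feats) else emptyFeatureTable()

  seq <- NULL
  if (length(origin_i)) {
    end_i <- grep("^//", lines)
    end_i <- end_i[end_i > origin_i[1]][1]
    if (is.na(end_i)) end_i <- length(lines) + 1L
    block <- lines[(origin_i[1] + 1L):(end_i - 1L)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(block, collapse = "")))
    if (nchar(seq) == 0L) seq <- NULL
  }
  if (!is.null(seq) && !is.na(declared_len) && nchar(seq) != declared_len)
    stop(sprintf("LOCUS declares %d bp but ORIGIN has %d", declared_len,
                 nchar(seq)))
  Mitogenome(ft, length = if (!is.null(seq)) nchar(seq) else declared_len,
             id = id, circular = circular, sequence = seq)
}

parseGenBankLocation <- function(loc, circular) {
  loc <- gsub("\\s", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",")[[1]]
    if (length(parts) != 2L || !circular)
      stop("unsupported join() location: ", loc)
    seg <- lapply(parts, parseSimpleSpan)
    if (seg[[2]]$start != 1L)
      stop("join() does not span the origin: ", loc)
    return(list(start = seg[[1]]$start, end = seg[[2]]$end, strand = strand))
  }
  span <- parseSimpleSpan(loc)
  list(start = span$start, end = span$end, strand = strand)
}

parseSimpleSpan <- function(loc) {
  m <- regmatches(loc, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", loc))[[1]]
  if (length(m) == 3L)
    return(list(start = as.integer(m[2]), end = as.integer(m[3])))
  if (grepl("^[0-9]+$", loc))
    return(list(start = as.integer(loc), end = as.integer(loc)))
  stop("unparseable GenBank location: ", loc)
}

#' Write a GenBank flat file
#'
#' @param mg a [Mitogenome-class] with sequence attached.
#' @param path output file path.
#' @param transl_table translation-table id written on CDS features.
#' @return \code{path}, invisibly.
#' @export
writeGenBank <- function(mg, path, transl_table = 9L) {
  if (is.null(genomeSequence(mg)))
    stop("GenBank output requires a sequence-bearing record")
  L <- genomeLength(mg)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                   recordId(mg), L,
                   if (isCircular(mg)) "circular" else "linear"),
           sprintf("DEFINITION  %s mitochondrion.", recordId(mg)),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L))
  ft <- features(mg)
  for (i in seq_len(nrow(ft))) {
    span <- if (ft$end[i] >= ft$start[i])
      sprintf("%d..%d", ft$start[i], ft$end[i])
    else sprintf("join(%d..%d,1..%d)", ft$start[i], L, ft$end[i])
    loc <- if (ft$strand[i] == "-") sprintf("complement(%s)", span) else span
    key <- switch(ft$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "misc_feature")
    out <- c(out, sprintf("     %-16s%s", key, loc),
             sprintf('                     /gene="%s"', ft$name[i]))
    if (ft$kind[i] == "PCG")
      out <- c(out, sprintf("                     /transl_table=%d",
                            transl_table))
    if (ft$kind[i] == "tRNA" && !is.na(ft$anticodon[i]))
      out <- c(out, sprintf('                     /anticodon="%s"',
                            ft$anticodon[i]))
  }
  out <- c(out, "ORIGIN")
  seqchr <- tolower(mg@sequence)
  starts <- seq(1L, nchar(seqchr), by = 60L)
  for (s in starts) {
    chunk <- substr(seqchr, s, min(s + 59L, nchar(seqchr)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  writeLines(c(out, "//"), path)
  invisible(path)
}

## ---- FASTA alignments -----------------------------------------------------

#' Read a FASTA alignment
#'
#' Reads a multi-FASTA file, uppercases bases, maps RNA \code{U} to
#' \code{T} (with a warning) and rejects ragged alignments.
#'
#' @param path file path.
#' @return A [Biostrings::DNAStringSet] in which all sequences have equal
#'   width; gaps (\code{-}) and \code{N} are preserved.
#' @export
readFastaAlignment <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (!length(raw)) stop("FASTA file contains no records")
  chr <- toupper(as.character(raw))
  if (any(grepl("U", chr, fixed = TRUE))) {
    warning("'U' bases normalized to 'T'")
    chr <- gsub("U", "T", chr, fixed = TRUE)
  }
  bad <- grepl("[^ACGTN-]", chr)
  if (any(bad))
    stop("alignment contains unsupported characters in: ",
         paste(names(raw)[bad], collapse = ", "))
  if (length(unique(nchar(chr))) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(raw)
  out
}

#' Write a FASTA alignment
#'
#' @param aln a [Biostrings::DNAStringSet] (or named character vector).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeFastaAlignment <- function(aln, path) {
  if (is.character(aln)) aln <- Biostrings::DNAStringSet(aln)
  Biostrings::writeXStringSet(aln, path)
  invisible(path)
}

## Alignment as a plain character matrix (rows = sequences).
alignmentMatrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  chr <- as.character(aln)
  if (length(unique(nchar(chr))) > 1L)
    stop("ragged alignment: sequences have unequal lengths")
  m <- do.call(rbind, strsplit(chr, ""))
  rownames(m) <- if (!is.null(names(chr))) names(chr)
    else paste0("seq", seq_along(chr))
  m
}
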