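## Comparative mitochondrial gene-order analysis on a signed, circular
## model: a gene order and its mirrored reading (the same circle traversed
## backwards with all orientations flipped) are one arrangement. Orders are
## canonicalized by rotating cox1 (the anchor conserved across
## Holothuroidea) to the front on the plus strand. Breakpoint distance
## counts the adjacencies of one order absent from the other; rearrangement
## events are classified by a single-event heuristic (single-gene
## translocation, segment inversion, contiguous multi-gene shift).

#' Normalize gene names to the controlled vocabulary
#'
#' Applies the shipped harmonization table (editable TSV at
#' \code{inst/extdata/gene_name_map.tsv}) mapping common database spellings
#' (MITOS anticodon-suffixed tRNAs, \code{COI}, \code{16S}, ...) onto the
#' canonical labels (\code{cox1..3}, \code{nad1..6}, \code{nad4l},
#' \code{atp6/8}, \code{cob}, \code{rrnS/L}, \code{trnX} with paralog
#' suffixes). Unrecognized names pass through lowercased.
#'
#' @param names character vector of gene names.
#' @param map optional two-column data.frame (\code{from}, \code{to})
#'   overriding the shipped table.
#' @return character vector of normalized names.
#' @export
normalizeGeneNames <- function(names, map = NULL) {
  if (is.null(map)) {
    tsv <- system.file("extdata", "gene_name_map.tsv", package = "mitochar",
                       mustWork = TRUE)
    map <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  }
  key <- tolower(trimws(names))
  idx <- match(key, tolower(map$from))
  out <- ifelse(is.na(idx), key, map$to[idx])
  out
}

canonicalOrderFrame <- function(sig) {
  stopifnot(is(sig, "GeneOrder"))
  sig@order
}

reverseOrderFrame <- function(o) {
  data.frame(name = rev(o$name),
             strand = ifelse(rev(o$strand) == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

rotateOrderFrame <- function(o, first) {
  n <- nrow(o)
  idx <- ((seq_len(n) + first - 2L) %% n) + 1L
  out <- o[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonicalize a gene order
#'
#' Rotates a circular order so the anchor gene (default \code{cox1}) comes
#' first; if the anchor sits on the minus strand the whole circle is read
#' backwards with all orientations flipped first, so the anchor always
#' reads \code{(anchor, +)}. Idempotent. Linear orders are only reversed
#' (never rotated).
#'
#' @param sig a [GeneOrder-class].
#' @param anchor anchor gene name; must occur exactly once.
#' @return A canonicalized [GeneOrder-class].
#' @export
canonicalizeOrder <- function(sig, anchor = "cox1") {
  o <- canonicalOrderFrame(sig)
  hits <- which(o$name == anchor)
  if (length(hits) != 1L)
    stop("anchor gene '", anchor, "' occurs ", length(hits),
         " times; supply a unique anchor via the 'anchor' argument")
  if (o$strand[hits] == "-") {
    o <- reverseOrderFrame(o)
    hits <- which(o$name == anchor)
  }
  if (sig@circular) {
    o <- rotateOrderFrame(o, hits)
  } else if (hits != 1L) {
    stop("linear order cannot be rotated to anchor '", anchor, "'")
  }
  new("GeneOrder", label = sig@label, order = o, circular = sig@circular)
}

## Canonical string form of one signed adjacency: an adjacency and its full
## reverse complement are the same adjacency.
adjacencyKey <- function(name1, strand1, name2, strand2) {
  fwd <- paste0(strand1, name1, ">", strand2, name2)
  flip <- function(s) ifelse(s == "+", "-", "+")
  rev <- paste0(flip(strand2), name2, ">", flip(strand1), name1)
  pmin(fwd, rev)
}

#' Signed adjacency set of a gene order
#'
#' The set of oriented neighbor pairs around the (circular) order,
#' normalized so that an adjacency and its reverse complement coincide.
#' Rotation- and mirror-invariant by construction.
#'
#' @param sig a [GeneOrder-class].
#' @return character vector of unique adjacency keys.
#' @export
adjacencySet <- function(sig) {
  o <- canonicalOrderFrame(sig)
  n <- nrow(o)
  if (n < 2L) return(character(0))
  i <- seq_len(if (sig@circular) n else n - 1L)
  j <- if (sig@circular) c(seq_len(n)[-1L], 1L) else i + 1L
  unique(adjacencyKey(o$name[i], o$strand[i], o$name[j], o$strand[j]))
}

restrictToShared <- function(a, b) {
  shared <- intersect(a@order$name, b@order$name)
  if (!length(shared))
    stop("gene orders share no genes")
  dropA <- setdiff(a@order$name, shared)
  dropB <- setdiff(b@order$name, shared)
  if (length(dropA) || length(dropB))
    warning("gene content differs; restricting to ", length(shared),
            " shared genes (dropped: ",
            paste(unique(c(dropA, dropB)), collapse = ", "), ")")
  sub <- function(sig) new("GeneOrder", label = sig@label,
                           order = sig@order[sig@order$name %in% shared, ,
                                             drop = FALSE],
                           circular = sig@circular)
  list(a = sub(a), b = sub(b))
}

#' Breakpoint distance between two gene orders
#'
#' Number of signed adjacencies of \code{a} absent from \code{b}, after
#' restricting both orders to their shared gene content (with a warning
#' when content differs). Zero iff the two circles are the same arrangement
#' (up to rotation and mirror reading).
#'
#' @param a,b [GeneOrder-class] objects.
#' @return non-negative integer.
#' @examples
#' x <- GeneOrder(c("cox1", "a", "b", "c"), "+")
#' y <- GeneOrder(c("cox1", "b", "a", "c"), "+")
#' breakpointDistance(x, y)
#' @export
breakpointDistance <- function(a, b) {
  r <- restrictToShared(a, b)
  adjA <- adjacencySet(r$a)
  adjB <- adjacencySet(r$b)
  length(setdiff(adjA, adjB))
}

orderKey <- function(sig, anchor = "cox1") {
  o <- canonicalizeOrder(sig, anchor)@order
  paste(paste0(o$strand, o$name), collapse = " ")
}

#' Group gene orders into arrangement classes
#'
#' Equivalence classes under identical canonical signed order (rotation and
#' mirror reading identified).
#'
#' @param sigs list of [GeneOrder-class] objects.
#' @param anchor anchor gene for canonicalization.
#' @return A list with \code{n_classes}, \code{classes} (list of label
#'   vectors) and \code{representatives} (one canonical [GeneOrder-class]
#'   per class).
#' @export
groupArrangements <- function(sigs, anchor = "cox1") {
  stopifnot(length(sigs) >= 1L)
  keys <- vapply(sigs, orderKey, character(1), anchor = anchor)
  groups <- split(seq_along(sigs), factor(keys, levels = unique(keys)))
  labels <- lapply(groups, function(ix)
    vapply(sigs[ix], function(s) s@label, character(1)))
  reps <- lapply(groups, function(ix) canonicalizeOrder(sigs[[ix[1]]], anchor))
  list(n_classes = length(groups), classes = unname(labels),
       representatives = unname(reps))
}

sameArrangement <- function(a, b, anchor = "cox1") {
  identical(orderKey(a, anchor), orderKey(b, anchor))
}

#' Apply a rearrangement event to a gene order
#'
#' Replays an event emitted by [classifyEvents()] on the canonical form of
#' \code{a}; used to verify that the classified event indeed transforms one
#' order into the other.
#'
#' @param a a [GeneOrder-class].
#' @param event one element of the \code{events} list from
#'   [classifyEvents()].
#' @return the transformed [GeneOrder-class].
#' @export
applyEvent <- function(a, event) {
  o <- canonicalizeOrder(a)@order
  out <- switch(event$kind,
    inversion = {
      i <- event$from; j <- event$to
      seg <- reverseOrderFrame(o[i:j, , drop = FALSE])
      rbind(if (i > 1L) o[1:(i - 1L), ], seg,
            if (j < nrow(o)) o[(j + 1L):nrow(o), ])
    },
    single_gene_translocation = ,
    multi_gene_shift = {
      i <- event$from; j <- event$to
      block <- o[i:j, , drop = FALSE]
      if (isTRUE(event$inverted)) block <- reverseOrderFrame(block)
      rest <- o[-(i:j), , drop = FALSE]
      p <- event$insert_after
      rbind(if (p >= 1L) rest[seq_len(p), ], block,
            if (p < nrow(rest)) rest[(p + 1L):nrow(rest), ])
    },
    stop("cannot replay event of kind '", event$kind, "'")
  )
  rownames(out) <- NULL
  new("GeneOrder", label = a@label, order = out, circular = a@circular)
}

#' Classify the rearrangement between two gene orders
#'
#' Single-event heuristics applied in fixed order on the canonical forms:
#' \enumerate{
#'   \item \code{single_gene_translocation}: moving (possibly flipping) one
#'     gene of \code{a} yields \code{b};
#'   \item \code{inversion}: reversing one contiguous segment of \code{a}
#'     (orientations flipped) yields \code{b};
#'   \item \code{multi_gene_shift}: relocating one contiguous block (of two
#'     or more genes, orientation preserved) yields \code{b};
#'   \item otherwise a single \code{unclassified} event carrying the
#'     breakpoint count.
#' }
#' Identical arrangements return an empty event list. Composite multi-event
#' histories deliberately fall through to \code{unclassified} rather than
#' guessing a scenario.
#'
#' @param a,b [GeneOrder-class] objects with identical gene content.
#' @return A list of events; each event is a list with \code{kind},
#'   \code{genes} and replay parameters (see [applyEvent()]).
#' @export
classifyEvents <- function(a, b) {
  if (!setequal(a@order$name, b@order$name))
    stop("classifyEvents() requires identical gene content")
  if (sameArrangement(a, b)) return(list())
  oa <- canonicalizeOrder(a)@order
  ob <- canonicalizeOrder(b)@order
  n <- nrow(oa)
  tryEvent <- function(event) {
    if (sameArrangement(applyEvent(a, event), b)) event else NULL
  }
  ## rotation-only circular equality of two signed orders (no mirror):
  ## distinguishes a true segment inversion from a single-gene move
  rotEqual <- function(o1, o2) {
    if (nrow(o1) != nrow(o2)) return(FALSE)
    k1 <- paste0(o1$strand, o1$name)
    k2 <- paste0(o2$strand, o2$name)
    grepl(paste0(" ", paste(k2, collapse = " "), " "),
          paste0(" ", paste(c(k1, k1), collapse = " "), " "), fixed = TRUE)
  }
  ## 1. single-gene translocation: removing one gene from both orders makes
  ##    them identical (up to rotation, reading direction kept)
  for (i in seq_len(n)) {
    g <- oa$name[i]
    if (sum(ob$name == g) != 1L) next
    if (!rotEqual(oa[-i, , drop = FALSE],
                  ob[ob$name != g, , drop = FALSE])) next
    for (p in 0L:(n - 1L)) {
      for (inv in c(FALSE, TRUE)) {
        ev <- list(kind = "single_gene_translocation", genes = g,
                   from = i, to = i, insert_after = p, inverted = inv)
        hit <- tryEvent(ev)
        if (!is.null(hit)) return(list(hit))
      }
    }
  }
  ## 2. inversion of one contiguous segment (length >= 2)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ev <- list(kind = "inversion", genes = oa$name[i:j], from = i, to = j)
      hit <- tryEvent(ev)
      if (!is.null(hit)) return(list(hit))
    }
  }
  ## 3. contiguous block shift (length >= 2, orientation preserved)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j - i + 1L >= n) next
      nrest <- n - (j - i + 1L)
      for (p in 0L:nrest) {
        ev <- list(kind = "multi_gene_shift", genes = oa$name[i:j],
                   from = i, to = j, insert_after = p, inverted = FALSE)
        hit <- tryEvent(ev)
        if (!is.null(hit)) return(list(hit))
      }
    }
  }
  list(list(kind = "unclassified", genes = character(0),
            breakpoints = breakpointDistance(a, b)))
}

#' Pairwise rearrangement report
#'
#' Shared adjacencies, breakpoints and classified events for a pair of
#' orders.
#'
#' @param a,b [GeneOrder-class] objects.
#' @param classify run [classifyEvents()] (requires equal gene content).
#' @return A list with \code{pair}, \code{shared_adjacencies},
#'   \code{breakpoints} and \code{events}.
#' @export
rearrangementReport <- function(a, b, classify = TRUE) {
  r <- restrictToShared(a, b)
  adjA <- adjacencySet(r$a); adjB <- adjacencySet(r$b)
  list(pair = c(a@label, b@label),
       shared_adjacencies = length(intersect(adjA, adjB)),
       breakpoints = length(setdiff(adjA, adjB)),
       events = if (classify && setequal(a@order$name, b@order$name))
         classifyEvents(a, b) else NULL)
}

#' Plain-text linear diagram of gene orders
#'
#' One line per order (or arrangement-class representative): the canonical
#' order with minus-strand genes prefixed by \code{-}.
#'
#' @param sigs list of [GeneOrder-class] objects.
#' @param anchor anchor gene.
#' @return character vector of lines.
#' @export
orderDiagram <- function(sigs, anchor = "cox1") {
  vapply(sigs, function(s) {
    o <- canonicalizeOrder(s, anchor)@order
    sprintf("%-20s %s", s@label,
            paste0(ifelse(o$strand == "-", "-", ""), o$name, collapse = " "))
  }, character(1))
}
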