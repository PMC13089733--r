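## Seeded synthetic-data generators. Two independent generators share one
## integer seed but derive separate streams, so adding calls to one never
## perturbs the other:
##   - simulateMitogenome(): an annotated circular genome realizing a
##     planned gene order, per-feature lengths, signed gap plan (overlaps by
##     coordinate arithmetic: a downstream feature simply starts inside its
##     upstream neighbor) and composition weights, with valid start codons
##     and complete-or-incomplete stops under translation table 9; plus a
##     truth table (exact gap vector, per-feature base counts, per-PCG codon
##     counts and peptide) computed from the final sequence by plain string
##     slicing.
##   - simulateHaplotypes(): an alignment built by replicating a reference
##     row per haplotype class and planting substitutions (infinite-sites by
##     default), with closed-form diversity truth by enumeration over class
##     pairs.

withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) %% 1000003L) * 2048L + stream)
  force(expr)
}

DEFAULT_WEIGHTS <- c(A = 0.341, C = 0.259, G = 0.149, T = 0.251)

## Codon bodies are drawn from sense codons only, so in-frame stops can only
## arise where one feature overwrites another's bases at an overlap
## junction. This pass finds such collateral in-frame stops and repairs them
## by mutating one non-forced base of the offending codon, re-checking all
## PCGs after each candidate edit.
repairInternalStops <- function(buf, forced, go, start, end, len, pcg_idx,
                                code) {
  bodyCodons <- function(buf, i) {
    s <- paste(buf[start[i]:end[i]], collapse = "")
    if (go$strand[i] == "-") s <- revcompChr(s)
    nc <- len[i] %/% 3L
    st <- seq(1L, by = 3L, length.out = nc)
    cd <- substring(s, st, st + 2L)
    if (len[i] %% 3L == 0L) cd <- cd[-nc]  # terminal complete stop
    cd
  }
  ## plus-strand positions of codon j of PCG i
  codonPositions <- function(i, j) {
    if (go$strand[i] == "+") (start[i] + 3L * (j - 1L)) + 0:2
    else (end[i] - 3L * (j - 1L)) - 0:2
  }
  countStops <- function(buf) sum(vapply(pcg_idx, function(i)
    sum(bodyCodons(buf, i) %in% code$stop_codons), integer(1)))
  for (iter in seq_len(100L)) {
    total <- countStops(buf)
    if (total == 0L) return(buf)
    fixed <- FALSE
    for (i in pcg_idx) {
      bad <- which(bodyCodons(buf, i) %in% code$stop_codons)
      if (!length(bad)) next
      for (pos in codonPositions(i, bad[1])) {
        if (forced[pos]) next
        for (b in setdiff(c("A", "C", "G", "T"), buf[pos])) {
          trial <- buf
          trial[pos] <- b
          if (countStops(trial) < total) {
            buf <- trial
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (fixed) break
    }
    if (!fixed)
      stop("gap plan creates an unrepairable in-frame stop at an overlap")
  }
  stop("in-frame stop repair did not converge")
}

#' Specification of a synthetic annotated mitogenome
#'
#' @param gene_order data.frame with columns \code{name}, \code{kind}
#'   (inferred from the name when absent) and \code{strand}.
#' @param length_plan integer vector of feature lengths (bp). For PCGs the
#'   length modulo 3 encodes the stop: 0 = complete 3 bp stop, 1 =
#'   incomplete \code{T}, 2 = incomplete \code{TA}.
#' @param gap_plan signed integer vector of length \code{n - 1}: the gap
#'   written between consecutive features (negative = overlap).
#' @param wraparound unannotated bp after the last feature (the putative
#'   control region).
#' @param weights genome-wide base sampling probabilities (named, A/C/G/T).
#' @param feature_weights optional list of per-feature weight overrides,
#'   keyed by feature index or name.
#' @param stop_plan optional character vector of complete stop codons per
#'   PCG (default \code{"TAA"}; only used where the length plan allows a
#'   complete stop).
#' @param id record label.
#' @return A validated list of class \code{genomeSpec}.
#' @export
genomeSpec <- function(gene_order, length_plan, gap_plan,
                       wraparound = 100L, weights = DEFAULT_WEIGHTS,
                       feature_weights = NULL, stop_plan = NULL,
                       id = "synthetic") {
  go <- as.data.frame(gene_order, stringsAsFactors = FALSE)
  if (!"kind" %in% names(go)) go$kind <- inferFeatureKind(go$name)
  if (!"strand" %in% names(go)) go$strand <- "+"
  n <- nrow(go)
  length_plan <- as.integer(length_plan)
  gap_plan <- as.integer(gap_plan)
  stopifnot(length(length_plan) == n, length(gap_plan) == n - 1L,
            all(length_plan >= 1L), wraparound >= 0L)
  if (any(go$kind == "PCG" & length_plan < 6L))
    stop("PCG lengths must be at least 6 bp")
  if (any(-gap_plan >= length_plan[-n]))
    stop("overlap exceeds upstream feature length")
  w <- weights[c("A", "C", "G", "T")] / sum(weights)
  pcgs <- which(go$kind == "PCG")
  if (is.null(stop_plan)) stop_plan <- rep("TAA", length(pcgs))
  stopifnot(length(stop_plan) == length(pcgs),
            all(stop_plan %in% c("TAA", "TAG")))
  structure(list(gene_order = go, length_plan = length_plan,
                 gap_plan = gap_plan, wraparound = as.integer(wraparound),
                 weights = w, feature_weights = feature_weights,
                 stop_plan = stop_plan, id = id),
            class = "genomeSpec")
}

specWeights <- function(spec, i) {
  fw <- spec$feature_weights
  if (!is.null(fw)) {
    key <- as.character(i)
    nm <- spec$gene_order$name[i]
    if (!is.null(fw[[key]])) return(fw[[key]][c("A", "C", "G", "T")] /
                                      sum(fw[[key]]))
    if (!is.null(fw[[nm]])) return(fw[[nm]][c("A", "C", "G", "T")] /
                                     sum(fw[[nm]]))
  }
  spec$weights
}

#' Simulate an annotated mitogenome with exact truth tables
#'
#' Realizes a [genomeSpec()]: coordinates follow the gap plan
#' (\code{start[i+1] = end[i] + gap[i] + 1}), spacer and wraparound bases
#' are drawn from the composition weights, non-coding features from their
#' feature weights, and each PCG is written on its coding strand as
#' \code{ATG} + random sense codons (no in-frame stops) + the planned
#' complete or incomplete stop. Overlaps are realized purely by coordinate
#' arithmetic (the downstream feature starts inside the upstream one);
#' after assembly every PCG start codon and stop is re-imposed in feature
#' order and the result re-audited, so a plan whose overlaps would destroy
#' a start/stop or create an in-frame stop is rejected rather than silently
#' emitted. Deterministic given \code{seed}.
#'
#' @param spec a [genomeSpec()].
#' @param seed integer seed.
#' @return A list with \code{record} (a sequence-bearing
#'   [Mitogenome-class]) and \code{truth}: \code{gap_plan},
#'   \code{gene_order}, \code{base_counts} (per-feature A/C/G/T count
#'   matrix on the plus-strand slice), \code{codons} (per-PCG ordered codon
#'   vectors, terminal stop included), \code{peptides} (translations,
#'   terminal stop dropped), \code{remainders} (incomplete stop fragments),
#'   \code{wraparound}.
#' @export
simulateMitogenome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genomeSpec"))
  withStream(seed, 1L, {
    go <- spec$gene_order
    n <- nrow(go)
    len <- spec$length_plan
    start <- integer(n); end <- integer(n)
    start[1] <- 1L; end[1] <- len[1]
    for (i in seq_len(n - 1L)) {
      start[i + 1L] <- end[i] + spec$gap_plan[i] + 1L
      end[i + 1L] <- start[i + 1L] + len[i + 1L] - 1L
      if (start[i + 1L] <= start[i])
        stop("gap plan makes feature ", i + 1L, " start before feature ", i)
    }
    L <- max(end) + spec$wraparound
    code <- geneticCode(9)

    ## base buffer, filled with genome-wide background first
    buf <- sample(names(spec$weights), L, replace = TRUE,
                  prob = spec$weights)
    drawCodons <- function(m, w) {
      if (m == 0L) return(character(0))
      p <- vapply(code$sense_codons, function(cd) {
        b <- strsplit(cd, "")[[1]]
        w[b[1]] * w[b[2]] * w[b[3]]
      }, numeric(1))
      sample(code$sense_codons, m, replace = TRUE, prob = p / sum(p))
    }
    coding <- vector("list", n)  # coding-strand string per feature
    pcg_idx <- which(go$kind == "PCG")
    stop_of <- stats::setNames(spec$stop_plan, pcg_idx)
    for (i in seq_len(n)) {
      w <- specWeights(spec, i)
      if (go$kind[i] == "PCG") {
        rem <- len[i] %% 3L
        stop_str <- switch(as.character(rem), `0` = stop_of[[as.character(i)]],
                           `1` = "T", `2` = "TA")
        m <- (len[i] - 3L - nchar(stop_str)) %/% 3L
        coding[[i]] <- paste0("ATG", paste(drawCodons(m, w), collapse = ""),
                              stop_str)
      } else {
        coding[[i]] <- paste(sample(names(w), len[i], replace = TRUE,
                                    prob = w), collapse = "")
      }
    }
    writeSlice <- function(buf, i, s) {
      plus <- if (go$strand[i] == "-") revcompChr(s) else s
      buf[start[i]:end[i]] <- strsplit(plus, "")[[1]]
      buf
    }
    for (i in seq_len(n)) buf <- writeSlice(buf, i, coding[[i]])
    ## re-impose PCG start codons and stops (overlapping neighbors may have
    ## overwritten them), tracking the forced positions
    forced <- logical(L)
    forcePlus <- function(buf, pos_first, s) {
      pos <- pos_first:(pos_first + nchar(s) - 1L)
      buf[pos] <- strsplit(s, "")[[1]]
      forced[pos] <<- TRUE
      buf
    }
    for (i in pcg_idx) {
      buf <- if (go$strand[i] == "+") forcePlus(buf, start[i], "ATG")
        else forcePlus(buf, end[i] - 2L, "CAT")
    }
    for (i in pcg_idx) {
      rem <- len[i] %% 3L
      stop_str <- if (rem == 0L) stop_of[[as.character(i)]]
        else substr(coding[[i]], len[i] - rem + 1L, len[i])
      buf <- if (go$strand[i] == "+")
        forcePlus(buf, end[i] - nchar(stop_str) + 1L, stop_str)
      else forcePlus(buf, start[i], revcompChr(stop_str))
    }
    buf <- repairInternalStops(buf, forced, go, start, end, len, pcg_idx,
                               code)
    seqchr <- paste(buf, collapse = "")

    ## truth by plain slicing of the final sequence
    sliceOf <- function(i) {
      s <- substr(seqchr, start[i], end[i])
      if (go$strand[i] == "-") revcompChr(s) else s
    }
    base_counts <- t(vapply(seq_len(n), function(i) {
      s <- substr(seqchr, start[i], end[i])
      ch <- strsplit(s, "")[[1]]
      c(A = sum(ch == "A"), C = sum(ch == "C"),
        G = sum(ch == "G"), T = sum(ch == "T"))
    }, integer(4)))
    rownames(base_counts) <- go$name
    codons <- list(); peptides <- list(); remainders <- list()
    for (i in pcg_idx) {
      cds <- sliceOf(i)
      nc <- len[i] %/% 3L
      st <- seq(1L, by = 3L, length.out = nc)
      cd <- substring(cds, st, st + 2L)
      rem <- if (len[i] %% 3L) substr(cds, nc * 3L + 1L, len[i]) else ""
      nm <- go$name[i]
      if (cd[1] != "ATG")
        stop("plan destroyed the start codon of ", nm)
      body <- if (rem == "") cd[-nc] else cd
      aas <- code$codon_map[body]
      if (any(aas == "*"))
        stop("plan created an in-frame stop in ", nm)
      if (rem == "" && !(cd[nc] %in% code$stop_codons))
        stop("plan destroyed the stop codon of ", nm)
      codons[[nm]] <- cd
      peptides[[nm]] <- paste(aas, collapse = "")
      remainders[[nm]] <- rem
    }
    ft <- data.frame(name = go$name, kind = go$kind, start = start,
                     end = end, strand = go$strand,
                     anticodon = NA_character_,
                     start_codon = ifelse(go$kind == "PCG", "ATG",
                                          NA_character_),
                     stop_codon = NA_character_, stringsAsFactors = FALSE)
    ft$stop_codon[pcg_idx] <- vapply(pcg_idx, function(i) {
      rem <- len[i] %% 3L
      if (rem == 0L) stop_of[[as.character(i)]]
      else remainders[[go$name[i]]]
    }, character(1))
    record <- Mitogenome(ft, length = L, id = spec$id, circular = TRUE,
                         sequence = seqchr)
    truth <- list(gap_plan = spec$gap_plan,
                  gene_order = go[c("name", "strand")],
                  base_counts = base_counts, codons = codons,
                  peptides = peptides, remainders = remainders,
                  wraparound = spec$wraparound, length = L)
    list(record = record, truth = truth)
  })
}

#' Genome spec mirroring the H. atra annotation geometry
#'
#' Builds a [genomeSpec()] whose gene order, feature lengths, signed gap
#' plan and stop-codon plan copy the packaged H. atra gene table (37
#' features, 151 bp unannotated wraparound), so the simulated genome
#' reproduces the published architecture counts (18 spacers, 7 overlaps) by
#' construction while carrying random sequence.
#'
#' @param weights genome-wide base weights.
#' @return A \code{genomeSpec}.
#' @export
hatraLikeGenomeSpec <- function(weights = DEFAULT_WEIGHTS) {
  mg <- hatraGeneTable()
  ft <- features(mg)
  lens <- featureLengths(mg)
  gaps <- ft$start[-1] - ft$end[-nrow(ft)] - 1L
  wrap <- genomeLength(mg) - max(ft$end)
  stops <- ft$stop_codon[ft$kind == "PCG"]
  stops[!stops %in% c("TAA", "TAG")] <- "TAA"  # incomplete stops: by length
  genomeSpec(ft[c("name", "kind", "strand")], lens, gaps,
             wraparound = wrap, weights = weights, stop_plan = stops,
             id = "synthetic-hatra-like")
}

#' Specification of a synthetic haplotype alignment
#'
#' @param n sample size.
#' @param L alignment length (sites).
#' @param class_sizes integer partition of \code{n}; the first class is the
#'   unmutated reference haplotype.
#' @param mutations per non-reference class, either an integer (number of
#'   substitutions to plant) or a data.frame with columns \code{site},
#'   \code{base}. Defaults to one substitution per non-reference class.
#' @param infinite_sites when planting automatically, use every site at
#'   most once across the whole plan (so S equals the number of planted
#'   substitutions); set \code{FALSE} to allow recurrent hits.
#' @return A validated list of class \code{haplotypeSpec}.
#' @export
haplotypeSpec <- function(n, L, class_sizes, mutations = NULL,
                          infinite_sites = TRUE) {
  class_sizes <- as.integer(class_sizes)
  stopifnot(sum(class_sizes) == n, all(class_sizes >= 1L), L >= 1L)
  C <- length(class_sizes)
  if (is.null(mutations)) mutations <- rep(1L, C - 1L)
  if (is.numeric(mutations)) {
    stopifnot(length(mutations) == C - 1L)
  } else {
    stopifnot(is.list(mutations), length(mutations) == C - 1L)
    for (m in mutations) {
      if (is.null(m)) next
      stopifnot(all(c("site", "base") %in% names(m)),
                all(m$site >= 1L), all(m$site <= L),
                !anyDuplicated(m$site))
    }
  }
  structure(list(n = as.integer(n), L = as.integer(L),
                 class_sizes = class_sizes, mutations = mutations,
                 infinite_sites = isTRUE(infinite_sites)),
            class = "haplotypeSpec")
}

#' Simulate a haplotype alignment with closed-form diversity truth
#'
#' Draws a random reference sequence, replicates it per haplotype class and
#' plants the specified (or automatically chosen) substitutions, then
#' computes the exact truth: H from the distinct mutation signatures, Hd by
#' Nei's unbiased formula on the class sizes, S from the per-site state
#' counts, k by direct enumeration over class pairs (sum of
#' size_i * size_j * Hamming(rep_i, rep_j) over C(n,2) pairs) and
#' Pi = k / L. All integer arithmetic, no sampling error.
#'
#' @param spec a [haplotypeSpec()].
#' @param seed integer seed.
#' @return A list with \code{alignment} (a named
#'   [Biostrings::DNAStringSet], rows grouped by class) and \code{truth}
#'   (n, L, H, Hd, S, k, Pi, d_within, class_sizes, plan).
#' @export
simulateHaplotypes <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "haplotypeSpec"))
  withStream(seed, 2L, {
    n <- spec$n; L <- spec$L
    sizes <- spec$class_sizes
    C <- length(sizes)
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    plan <- spec$mutations
    if (is.numeric(plan)) {
      counts <- as.integer(plan)
      total <- sum(counts)
      pool <- if (spec$infinite_sites) sample.int(L, total)
        else sample.int(L, total, replace = TRUE)
      if (spec$infinite_sites && total > L)
        stop("infinite-sites plan needs at most L substitutions")
      splits <- rep(seq_along(counts), counts)
      plan <- lapply(seq_along(counts), function(j) {
        sites <- pool[splits == j]
        data.frame(site = sites,
                   base = vapply(sites, function(s)
                     sample(setdiff(c("A", "C", "G", "T"), ref[s]), 1L),
                     character(1)),
                   stringsAsFactors = FALSE)
      })
    }
    reps <- matrix(ref, nrow = C, ncol = L, byrow = TRUE)
    for (j in seq_len(C - 1L)) {
      p <- plan[[j]]
      if (is.null(p) || !nrow(p)) next
      if (any(p$base == ref[p$site]))
        stop("mutation plan replants the reference base")
      reps[j + 1L, p$site] <- p$base
    }
    ## truth: aggregate identical representatives into haplotype classes
    key <- apply(reps, 1L, paste, collapse = "")
    hap_sizes <- as.integer(tapply(sizes, factor(key, levels = unique(key)),
                                   sum))
    H <- length(hap_sizes)
    Hd <- if (n >= 2L) (n / (n - 1)) * (1 - sum((hap_sizes / n)^2)) else 0
    state_counts <- vapply(seq_len(L), function(s)
      length(unique(reps[, s][sizes > 0L])), integer(1))
    S <- sum(state_counts >= 2L)
    total_diff <- 0
    if (C >= 2L) {
      for (i in seq_len(C - 1L)) {
        for (j in (i + 1L):C) {
          total_diff <- total_diff +
            sizes[i] * sizes[j] * sum(reps[i, ] != reps[j, ])
        }
      }
    }
    k <- total_diff / choose(n, 2)
    rows <- reps[rep(seq_len(C), sizes), , drop = FALSE]
    aln <- Biostrings::DNAStringSet(apply(rows, 1L, paste, collapse = ""))
    names(aln) <- sprintf("hap%d_%d", rep(seq_len(C), sizes),
                          unlist(lapply(sizes, seq_len)))
    truth <- list(n = n, L = L, H = H, Hd = Hd, S = as.integer(S), k = k,
                  Pi = k / L, d_within = k / L,
                  class_sizes = sort(hap_sizes, decreasing = TRUE),
                  plan = plan)
    list(alignment = aln, truth = truth)
  })
}
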