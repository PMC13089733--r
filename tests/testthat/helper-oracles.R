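# Independent oracles used across the suite. These deliberately use the
# dumbest correct formulation (character loops, pairwise double loops,
# exhaustive enumeration) or an unrelated library implementation
# (Biostrings), never the package's own code paths.

# character-tally oracle for base composition
bruteBaseCounts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  c(A = sum(ch == "A"), C = sum(ch == "C"),
    G = sum(ch == "G"), T = sum(ch == "T"))
}

# O(n^2 L) pairwise-difference oracle for k
bruteMeanPairwiseDiff <- function(m) {
  n <- nrow(m)
  total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + sum(m[i, ] != m[j, ])
    }
  }
  total / choose(n, 2)
}

# per-column scan oracle for segregating sites
bruteSegregatingSites <- function(m) {
  sum(vapply(seq_len(ncol(m)), function(s)
    length(unique(m[, s])) >= 2L, logical(1)))
}

# Biostrings reverse complement as the revcomp oracle
bsRevcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all signed circular gene orders over `genes`, with the first gene fixed
# forward (one representative per rotation; mirrors excluded by the fixed
# sign, see the acceptance test)
enumerateSignedOrders <- function(genes) {
  rest <- genes[-1]
  perms <- permutations(length(rest))
  signs <- as.matrix(expand.grid(rep(list(c("+", "-")), length(rest))))
  out <- list()
  for (p in seq_len(nrow(perms))) {
    for (s in seq_len(nrow(signs))) {
      out[[length(out) + 1L]] <- GeneOrder(
        c(genes[1], rest[perms[p, ]]),
        c("+", unname(signs[s, ])),
        label = sprintf("p%d_s%d", p, s))
    }
  }
  out
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow = nrow(sub)))
  }))
}

# random haplotype spec for property sweeps
randomHaplotypeSpec <- function(seed) {
  set.seed(seed)
  C <- sample(2:6, 1)
  sizes <- as.integer(rmultinom(1, size = sample(6:30, 1) - C,
                                prob = rep(1, C))) + 1L
  n <- sum(sizes)
  L <- sample(50:300, 1)
  muts <- sample(1:4, C - 1L, replace = TRUE)
  while (sum(muts) > L) muts <- pmax(1L, muts - 1L)
  haplotypeSpec(n, L, sizes, mutations = muts)
}

# tiny sequence-bearing record built by hand (no generator involvement)
toyRecord <- function(seq, features, circular = TRUE, id = "toy") {
  Mitogenome(features, length = nchar(seq), id = id, circular = circular,
             sequence = seq)
}
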