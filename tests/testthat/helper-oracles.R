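# Independent brute-force oracles used across the suite. These deliberately
# re-derive everything from first principles (genetic-code lookups, explicit
# strand construction, exhaustive enumeration) rather than calling the
# package's own fast paths.

GC <- Biostrings::GENETIC_CODE

ALL_CODONS <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste,
                         collapse = ""))

# Third bases reachable synonymously from a codon, by genetic-code lookup.
bf_third_options <- function(codon) {
  pre <- substr(codon, 1, 2)
  b <- c("A", "C", "G", "T")
  b[GC[paste0(pre, b)] == GC[codon]]
}

bf_codons <- function(seq) {
  s <- as.character(seq)
  starts <- seq(1, nchar(s), by = 3)
  substring(s, starts, starts + 2)
}

bf_translate <- function(seq) paste(GC[bf_codons(seq)], collapse = "")

bf_gc3 <- function(seq) {
  mean(substr(bf_codons(seq), 3, 3) %in% c("G", "C"))
}

# Exact distribution over all synonymous variants under the gc3 rule:
# P(GC option) = g / #GC options, P(AT option) = (1 - g) / #AT options,
# independently per codon.
oracle_gc3_probs <- function(seq) {
  g <- bf_gc3(seq)
  per_codon <- lapply(bf_codons(seq), function(cod) {
    opts <- bf_third_options(cod)
    is_gc <- opts %in% c("G", "C")
    p <- if (length(opts) == 1) 1 else
      ifelse(is_gc, g / sum(is_gc), (1 - g) / sum(!is_gc))
    stats::setNames(p, paste0(substr(cod, 1, 2), opts))
  })
  combine_codon_probs(per_codon)
}

# Exact distribution under the dn23 rule: weights from the subject's
# positions-2-3 dinucleotide frequencies, normalized per codon.
oracle_dn23_probs <- function(seq) {
  cods <- bf_codons(seq)
  dn <- table(substr(cods, 2, 3))
  f <- function(d) if (d %in% names(dn)) dn[[d]] / length(cods) else 0
  per_codon <- lapply(cods, function(cod) {
    opts <- bf_third_options(cod)
    w <- vapply(paste0(substr(cod, 2, 2), opts), f, numeric(1))
    p <- if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
    stats::setNames(p, paste0(substr(cod, 1, 2), opts))
  })
  combine_codon_probs(per_codon)
}

combine_codon_probs <- function(per_codon) {
  grid <- expand.grid(lapply(per_codon, names), stringsAsFactors = FALSE)
  prob <- Reduce(`*`, lapply(seq_along(per_codon), function(i)
    per_codon[[i]][grid[[i]]]))
  seqs <- apply(grid, 1, paste, collapse = "")
  tapply(as.numeric(prob), seqs, sum)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# Exact n3 distribution: uniform over the product of within-class
# permutations of third positions (duplicate arrangements aggregate mass).
oracle_n3_probs <- function(seq) {
  cods <- bf_codons(seq)
  thirds <- substr(cods, 3, 3)
  opts <- lapply(cods, bf_third_options)
  cls_key <- vapply(opts, function(o) paste(sort(o), collapse = ""),
                    character(1))
  arrangements <- list(stats::setNames(thirds, NULL))
  probs <- 1
  for (key in unique(cls_key[lengths(opts) > 1])) {
    idx <- which(cls_key == key & lengths(opts) > 1)
    P <- all_perms(length(idx))
    new_arr <- list(); new_p <- numeric(0)
    for (a in seq_along(arrangements)) {
      for (r in seq_len(nrow(P))) {
        arr <- arrangements[[a]]
        arr[idx] <- thirds[idx][P[r, ]]
        new_arr <- c(new_arr, list(arr))
        new_p <- c(new_p, probs[a] / nrow(P))
      }
    }
    arrangements <- new_arr; probs <- new_p
  }
  seqs <- vapply(arrangements, function(arr)
    paste(substr(cods, 1, 2), arr, sep = "", collapse = ""), character(1))
  tapply(probs, seqs, sum)
}

IUPAC_ORACLE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A","G"), Y = c("C","T"), S = c("C","G"), W = c("A","T"),
  K = c("G","T"), M = c("A","C"), B = c("C","G","T"), D = c("A","G","T"),
  H = c("A","C","T"), V = c("A","C","G"), N = c("A","C","G","T"))

IUPAC_COMPLEMENT <- c(A="T", C="G", G="C", T="A", R="Y", Y="R", S="S",
                      W="W", K="M", M="K", B="V", V="B", D="H", H="D",
                      N="N")

bf_revcomp <- function(s) {
  paste(rev(IUPAC_COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

# Naive two-strand scanner: scans the pattern over the top strand and over
# an explicitly constructed bottom strand, mapping bottom coordinates back.
naive_scan <- function(seq, pattern, target_index,
                       strand = c("both", "top", "bottom")) {
  strand <- match.arg(strand)
  s <- as.character(seq)
  n <- nchar(s)
  L <- nchar(pattern)
  pat <- strsplit(pattern, "")[[1]]
  match_at <- function(str, start) {
    all(mapply(function(p, c) c %in% IUPAC_ORACLE[[p]],
               pat, strsplit(substr(str, start, start + L - 1), "")[[1]]))
  }
  out <- data.frame(strand = character(0), position = integer(0))
  if (strand %in% c("top", "both") && n >= L) {
    for (i in seq_len(n - L + 1)) {
      if (match_at(s, i)) {
        out <- rbind(out, data.frame(strand = "top",
                                     position = i - 1 + target_index))
      }
    }
  }
  if (strand %in% c("bottom", "both") && n >= L) {
    bottom <- bf_revcomp(s)
    for (i in seq_len(n - L + 1)) {
      if (match_at(bottom, i)) {
        # bottom-strand 0-based index of the mutated C, mapped to top
        out <- rbind(out, data.frame(
          strand = "bottom",
          position = n - 1 - (i - 1 + target_index)))
      }
    }
  }
  out
}

# Random in-frame CDS built independently of the package's simulator.
random_seq <- function(n_codons, stop_free = TRUE) {
  pool <- if (stop_free) ALL_CODONS[GC[ALL_CODONS] != "*"] else ALL_CODONS
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}

# Goodness-of-fit of sampled sequences against an exact distribution.
gof_pvalue <- function(draws, probs) {
  obs <- table(factor(draws, levels = names(probs)))
  keep <- probs > 0
  stopifnot(all(obs[!keep] == 0))
  suppressWarnings(stats::chisq.test(obs[keep], p = probs[keep] /
                                       sum(probs[keep]))$p.value)
}

ALL_DINUCS <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"),
                              paste0))

# positions-2-3 dinucleotide frequency vector of a CDS, over all 16 dinucs
dinuc_freq_23 <- function(s) {
  cods <- bf_codons(s)
  as.numeric(table(factor(substr(cods, 2, 3), levels = ALL_DINUCS))) /
    length(cods)
}

# random CDS over sense codons excluding Met/Trp, so no codon slot is
# immutable under synonymous shuffling
fixed_free_seq <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(ALL_CODONS[GC[ALL_CODONS] != "*"], c("ATG", "TGG"))
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}
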