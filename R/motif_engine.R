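# Motif scanning and deamination simulation. A motif is an IUPAC pattern
# with a designated target cytidine; an occurrence on the top strand implies
# a C>T transition at the target, an occurrence on the bottom strand
# (scanned as the reverse complement of the pattern against the top strand)
# implies a G>A transition at the mirrored top-strand position. Replacement
# (nonsynonymous) transitions are those single-base changes that alter the
# encoded amino acid, with stop<->sense changes counted as replacements.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param s Single IUPAC string.
#' @return The reverse complement, with ambiguity codes mapped through the
#'   standard IUPAC complement table (R to Y, W to W, H to D, ...).
#' @examples
#' reverse_complement("TAC") # "GTA"
#' reverse_complement("WRC") # "GYW"
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (grepl("[^ACGTRYSWKMBDHVN]", toupper(s))) {
    stop("invalid IUPAC character in ", sQuote(s), call. = FALSE)
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Define a mutation motif
#'
#' A motif couples an IUPAC pattern with the 0-based offset of the
#' deaminated cytidine (`target_index`, which must point at a literal `C`)
#' and a strand mode. When `target_index` is omitted it defaults to the
#' 3'-most literal `C` in the pattern — the convention of deaminase motif
#' tables (TC, TTC, WRC, SYC all place the mutated C at the 3' end) which
#' for `CG` correctly picks position 0.
#'
#' @param pattern IUPAC string over \{A,C,G,T,R,Y,S,W,H,N,...\}, length >= 2,
#'   containing at least one literal `C`.
#' @param target_index 0-based offset of the target cytidine.
#' @param strand One of `"both"` (default), `"top"`, `"bottom"`.
#' @param name Label used in report keys; defaults to the pattern.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec("TAC")            # NNC-style motif, target at offset 2
#' motif_spec("WRC", strand = "top")
#' @export
motif_spec <- function(pattern, target_index = NULL,
                       strand = c("both", "top", "bottom"), name = pattern) {
  strand <- match.arg(strand)
  pattern <- toupper(pattern)
  if (nchar(pattern) < 2L) {
    stop("motif pattern must have length >= 2", call. = FALSE)
  }
  if (grepl("[^ACGTRYSWKMBDHVN]", pattern)) {
    stop("invalid IUPAC character in pattern ", sQuote(pattern),
         call. = FALSE)
  }
  chars <- strsplit(pattern, "")[[1]]
  if (is.null(target_index)) {
    cpos <- which(chars == "C")
    if (length(cpos) == 0L) {
      stop("pattern ", sQuote(pattern), " contains no literal C; ",
           "a deamination target is required", call. = FALSE)
    }
    target_index <- max(cpos) - 1L
  }
  target_index <- as.integer(target_index)
  if (target_index < 0L || target_index >= nchar(pattern) ||
      chars[target_index + 1L] != "C") {
    stop("target_index ", target_index, " of pattern ", sQuote(pattern),
         " does not point at a literal C", call. = FALSE)
  }
  structure(list(pattern = pattern, target_index = target_index,
                 strand = strand, name = name),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("<motif_spec> ", x$name, ": ", x$pattern, " (target C at offset ",
      x$target_index, ", strand ", x$strand, ")\n", sep = "")
  invisible(x)
}

#' The default motif vocabulary
#'
#' All 4 NC and 16 NNC motifs (N = any base), the AID hotspot WRC, the AID
#' coldspot SYC, and CG (CpG dinucleotides) — 23 motifs, all scanned on both
#' strands.
#'
#' @return List of [motif_spec()] objects, length 23.
#' @export
default_motif_set <- function() {
  nc <- paste0(BASES, "C")
  nnc <- as.vector(outer(BASES, paste0(BASES, "C"), paste0))
  pats <- c(nc, nnc, "WRC", "SYC", "CG")
  lapply(pats, motif_spec)
}

# Shared scanning core. For a character vector of equal-frame sequences,
# returns occurrence tables per sequence for one motif. Biostrings does the
# IUPAC matching (fixed = FALSE expands ambiguity codes in the pattern);
# overlapping matches are all reported.
scan_set <- function(seqs, motif) {
  stopifnot(inherits(motif, "motif_spec"))
  subj <- Biostrings::DNAStringSet(seqs)
  L <- nchar(motif$pattern)
  res <- list()
  if (motif$strand %in% c("top", "both")) {
    m <- Biostrings::vmatchPattern(motif$pattern, subj, fixed = FALSE)
    st <- IRanges::start(m)
    res$top <- lapply(st, function(s) s - 1L + motif$target_index)
  }
  if (motif$strand %in% c("bottom", "both")) {
    rc <- reverse_complement(motif$pattern)
    m <- Biostrings::vmatchPattern(rc, subj, fixed = FALSE)
    st <- IRanges::start(m)
    res$bottom <- lapply(st, function(s) s - 1L + (L - 1L - motif$target_index))
  }
  res
}

#' Locate motif occurrences on both strands
#'
#' Top-strand occurrences are all (possibly overlapping) matches of the
#' pattern; each implies a C>T change at top-strand position
#' `match_start + target_index`. Bottom-strand occurrences are matches of
#' the reverse-complemented pattern on the top strand; each implies a G>A
#' change at `match_start + (len - 1 - target_index)`. Positions are 0-based
#' on the top strand. Matches overhanging the sequence ends are not
#' considered (linear topology).
#'
#' @param seq A [coding_sequence()] or plain ACGT string.
#' @param motif A [motif_spec()].
#' @return A data frame with columns `strand` (`"top"`/`"bottom"`) and
#'   `position` (0-based top-strand index of the mutated base), ordered by
#'   position within strand.
#' @examples
#' find_occurrences("TACTAC", motif_spec("TAC", strand = "top"))
#' @export
find_occurrences <- function(seq, motif) {
  s <- as_cds_string(seq)
  sc <- scan_set(s, motif)
  top <- if (is.null(sc$top)) integer() else sc$top[[1]]
  bot <- if (is.null(sc$bottom)) integer() else sc$bottom[[1]]
  data.frame(
    strand = rep(c("top", "bottom"), c(length(top), length(bot))),
    position = c(top, bot)
  )
}

#' Count motif occurrences
#'
#' @inheritParams find_occurrences
#' @return Integer occurrence count under the motif's strand mode.
#' @examples
#' count_motifs("TACGTA", motif_spec("TAC")) # 2 (one per strand)
#' @export
count_motifs <- function(seq, motif) {
  nrow(find_occurrences(seq, motif))
}

# Vectorized replacement-transition classification for a set of occurrences
# described by parallel vectors: seqs (character), seq_index, position
# (0-based), strand. Returns logical: does the implied transition change the
# encoded amino acid?
is_replacement <- function(seqs, seq_index, position, strand) {
  if (length(position) == 0L) return(logical())
  codon_start <- (position %/% 3L) * 3L + 1L # 1-based
  codon <- substring(seqs[seq_index], codon_start, codon_start + 2L)
  offset <- position + 1L - codon_start # 0,1,2 within codon
  repl <- ifelse(strand == "top", "T", "A")
  mutated <- paste0(substr(codon, 1L, offset), repl,
                    substr(codon, offset + 2L, 3L))
  unname(GENETIC_CODE_TABLE[codon] != GENETIC_CODE_TABLE[mutated])
}

#' Count replacement (nonsynonymous) transitions at motif targets
#'
#' Simulates the canonical deamination outcome at every occurrence — C>T on
#' the top strand, G>A projected from the bottom strand — and counts the
#' occurrences whose single-base change alters the encoded amino acid.
#' Changes that create or destroy a stop codon count as replacements.
#'
#' @inheritParams find_occurrences
#' @return Integer, at most [count_motifs()].
#' @examples
#' count_replacement_transitions("TAC", motif_spec("TAC")) # TAC>TAT is silent
#' @export
count_replacement_transitions <- function(seq, motif) {
  s <- as_cds_string(seq)
  occ <- find_occurrences(s, motif)
  sum(is_replacement(s, rep(1L, nrow(occ)), occ$position, occ$strand))
}

#' Motif metrics triple for one sequence
#'
#' @inheritParams find_occurrences
#' @return A one-row data frame with `count` (motif occurrences), `rep_tr`
#'   (replacement transitions) and `rep_tr_frac` (their ratio, `NA` when the
#'   count is zero).
#' @examples
#' motif_metrics("TTACGG", motif_spec("TAC"))
#' @export
motif_metrics <- function(seq, motif) {
  s <- as_cds_string(seq)
  metrics_for_set(s, motif)
}

# Count / repTr / fraction for every sequence in a replicate set, one motif.
# This is the hot path: two vmatchPattern calls for the whole set, then
# vectorized codon mutation.
metrics_for_set <- function(seqs, motif) {
  sc <- scan_set(seqs, motif)
  n <- length(seqs)
  pos <- integer(); idx <- integer(); strand <- character()
  if (!is.null(sc$top)) {
    len <- lengths(sc$top)
    pos <- c(pos, unlist(sc$top, use.names = FALSE))
    idx <- c(idx, rep.int(seq_len(n), len))
    strand <- c(strand, rep.int("top", sum(len)))
  }
  if (!is.null(sc$bottom)) {
    len <- lengths(sc$bottom)
    pos <- c(pos, unlist(sc$bottom, use.names = FALSE))
    idx <- c(idx, rep.int(seq_len(n), len))
    strand <- c(strand, rep.int("bottom", sum(len)))
  }
  count <- tabulate(idx, nbins = n)
  nonsyn <- is_replacement(seqs, idx, pos, strand)
  rep_tr <- tabulate(idx[nonsyn], nbins = n)
  frac <- ifelse(count > 0L, rep_tr / count, NA_real_)
  data.frame(count = count, rep_tr = rep_tr, rep_tr_frac = frac)
}
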