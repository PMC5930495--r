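# Synthetic-CDS generators and exhaustive enumeration. These support
# controlled experiments: null subjects with a prescribed GC3, positive
# controls with a planted motif depletion, and the exact synonymous-sequence
# space for small inputs.

SENSE_CODONS <- names(CODON_CLASS)[GENETIC_CODE_TABLE[names(CODON_CLASS)] != "*"]

#' Generate a random in-frame coding sequence
#'
#' Codons are drawn from the 61 sense codons with third positions weighted
#' toward the requested GC3 (using the same class-wise mass-splitting rule
#' as the gc3 shuffle), then third positions are nudged by synonymous swaps
#' until the realized GC3 is within `tol` of the target (or no synonymous
#' swap can move it closer). The result contains no stop codons unless
#' `stop_free = FALSE`.
#'
#' @param n_codons Number of codons (>= 2).
#' @param gc3 Target third-position GC fraction in \[0, 1\].
#' @param seed Optional integer seed.
#' @param tol Acceptable |realized - target| GC3 deviation (default 0.05).
#' @param stop_free Exclude stop codons entirely.
#' @param id Identifier for the resulting sequence.
#' @return A [coding_sequence()].
#' @examples
#' random_cds(100, gc3 = 0.6, seed = 1)
#' @export
random_cds <- function(n_codons, gc3 = 0.5, seed = NULL, tol = 0.05,
                       stop_free = TRUE, id = "synthetic") {
  stopifnot(n_codons >= 2, gc3 >= 0, gc3 <= 1)
  if (!is.null(seed)) set.seed(seed)
  pool <- if (stop_free) SENSE_CODONS else names(CODON_CLASS)
  third <- substr(pool, 3L, 3L)
  cls <- classify_codon(pool)
  w <- vapply(seq_along(pool), function(i) {
    if (cls[i] == "FIXED") return(1)
    opts <- CLASS_THIRD_POSITIONS[[cls[i]]]
    is_gc <- opts %in% c("G", "C")
    if (third[i] %in% c("G", "C")) gc3 / sum(is_gc) else
      (1 - gc3) / sum(!is_gc)
  }, numeric(1))
  codons <- sample(pool, n_codons, replace = TRUE, prob = w)

  # nudge third positions toward the target by random synonymous swaps
  is_gc3 <- function(cod) substr(cod, 3L, 3L) %in% c("G", "C")
  for (step in seq_len(4L * n_codons)) {
    dev <- mean(is_gc3(codons)) - gc3
    if (abs(dev) <= tol) break
    want_gc <- dev < 0
    cl <- classify_codon(codons)
    movable <- which(cl != "FIXED" & (is_gc3(codons) != want_gc) &
                       vapply(cl, function(x)
                         any((CLASS_THIRD_POSITIONS[[x]] %in%
                                c("G", "C")) == want_gc), logical(1)))
    if (length(movable) == 0L) break
    i <- movable[sample.int(length(movable), 1L)]
    opts <- synonymous_options(codons[i])
    opts <- opts[is_gc3(opts) == want_gc]
    codons[i] <- opts[sample.int(length(opts), 1L)]
  }
  coding_sequence(paste(codons, collapse = ""), id = id)
}

#' Deplete a motif by synonymous codon swaps
#'
#' A positive-control constructor: greedily replaces codons with synonymous
#' third-position variants whenever the replacement strictly lowers the
#' motif's occurrence count (both strands respected), until at most
#' `(1 - strength)` of the original occurrences remain or no synonymous swap
#' helps. Because only synonymous swaps are used, the depleted sequence
#' stays inside the support of every shuffle null, so downstream
#' under-representation tests remain fair.
#'
#' @param seq A [coding_sequence()] or plain ACGT string.
#' @param motif A [motif_spec()].
#' @param strength Fraction of original occurrences to remove, in \[0, 1\].
#' @return A [coding_sequence()] with the same translation as the input.
#' @export
deplete_motif <- function(seq, motif, strength = 1) {
  stopifnot(inherits(motif, "motif_spec"), strength >= 0, strength <= 1)
  s <- as_cds_string(seq)
  orig_count <- count_motifs(s, motif)
  target <- ceiling((1 - strength) * orig_count)
  L <- nchar(motif$pattern)
  n_codons <- nchar(s) %/% 3L
  repeat {
    current <- count_motifs(s, motif)
    if (current <= target) break
    occ <- find_occurrences(s, motif)
    improved <- FALSE
    for (k in seq_len(nrow(occ))) {
      start <- if (occ$strand[k] == "top") occ$position[k] - motif$target_index
        else occ$position[k] - (L - 1L - motif$target_index)
      codon_idx <- unique(pmax(0L, pmin(n_codons - 1L,
                                        (start:(start + L - 1L)) %/% 3L)))
      for (ci in codon_idx) {
        cod <- substr(s, 3L * ci + 1L, 3L * ci + 3L)
        for (opt in setdiff(synonymous_options(cod), cod)) {
          cand <- paste0(substr(s, 1L, 3L * ci), opt,
                         substr(s, 3L * ci + 4L, nchar(s)))
          if (count_motifs(cand, motif) < current) {
            s <- cand
            improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (improved) break
    }
    if (!improved) break
  }
  coding_sequence(s, id = paste0(if (inherits(seq, "coding_sequence"))
    attr(seq, "id") else "", "_depleted_", motif$name))
}

#' Enumerate every synonymous variant of a small sequence
#'
#' All sequences sharing the input's translation with codon positions 1-2
#' held fixed — the exact sample space of the three shuffle methods. Guarded
#' against combinatorial explosion.
#'
#' @param seq A [coding_sequence()] or plain ACGT string.
#' @param limit Maximum number of variants to enumerate (guard).
#' @param freeze_stops Passed to [synonymous_options()].
#' @return Character vector of sequences (includes the input).
#' @examples
#' enumerate_synonymous("ATTGAA") # 3 x 2 = 6 variants
#' @export
enumerate_synonymous <- function(seq, limit = 1e5, freeze_stops = FALSE) {
  codons <- split_codons(seq)
  opts <- lapply(codons, synonymous_options, freeze_stops = freeze_stops)
  total <- prod(lengths(opts))
  if (total > limit) {
    stop("enumeration would produce ", format(total, big.mark = ","),
         " sequences (limit ", format(limit, big.mark = ","),
         "); use a shorter input", call. = FALSE)
  }
  grid <- expand.grid(opts, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}
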