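# Synonymous-shuffle null models. All three schemes keep codon positions 1-2
# (hence the amino-acid sequence) untouched and resample only third
# positions, each correcting for a different compositional covariate:
#   gc3  - third positions drawn to match the subject's third-position GC
#          content in expectation
#   n3   - third positions permuted within degeneracy classes, preserving
#          base composition exactly
#   dn23 - third positions drawn proportionally to the subject's
#          positions-2-3 dinucleotide frequencies
# A "shuffle plan" precomputes everything that depends only on the subject
# (classes, GC3, dinucleotide table, per-class codon indices) so that
# replicate generation is a cheap vectorized draw.

SHUFFLE_METHODS <- c("gc3", "n3", "dn23")

#' Precompute a shuffle plan for a subject sequence
#'
#' Classifies every codon, records which are mutable, and computes the two
#' sequence-wide statistics the draw rules need: the third-position GC
#' fraction (for `gc3`) and the positions-2-3 dinucleotide frequency table
#' (for `dn23`). FIXED codons contribute to both statistics — they are part
#' of the sequence's composition — but are never altered.
#'
#' @param seq A [coding_sequence()] or plain in-frame ACGT string.
#' @param freeze_stops Treat TAA/TAG as immutable (see [classify_codon()]).
#' @param gc3_include_fixed Include third positions of FIXED codons when
#'   computing the GC3 statistic used by the `gc3` rule. On by default: the
#'   statistic is defined over all codons of the sequence.
#' @return An object of class `shuffle_plan`.
#' @export
shuffle_plan <- function(seq, freeze_stops = FALSE, gc3_include_fixed = TRUE) {
  codons <- split_codons(seq)
  third <- substr(codons, 3L, 3L)
  second <- substr(codons, 2L, 2L)
  cls <- classify_codon(codons, freeze_stops = freeze_stops)

  gc3_mask <- if (gc3_include_fixed) rep(TRUE, length(codons)) else
    cls != "FIXED"
  g <- mean(third[gc3_mask] %in% c("G", "C"))

  # dinucleotide frequencies over (position 2, position 3) of every codon
  dinuc <- paste0(second, third)
  all_dinucs <- as.vector(outer(BASES, BASES, paste0))
  dn_freq <- table(factor(dinuc, levels = all_dinucs)) / length(dinuc)

  structure(list(
    codons = codons, second = second, third = third, class = cls,
    g = g, dn_freq = as.numeric(dn_freq), dn_names = all_dinucs,
    n_codons = length(codons)
  ), class = "shuffle_plan")
}

#' Per-option gc3 draw probabilities
#'
#' The gc3 rule splits the total probability mass `g` (the subject's
#' third-position GC fraction) uniformly over a codon's G/C synonymous
#' options and the mass `1 - g` uniformly over its A/T options. For an Ile
#' codon (class H: A/C/T) in a sequence with GC3 = 0.6 this yields
#' P(ATC) = 0.6 and P(ATT) = P(ATA) = 0.2; for a two-codon R or Y family it
#' reduces to P(G-or-C option) = g.
#'
#' @inheritParams shuffle_plan
#' @return A data frame with one row per (codon slot, synonymous option):
#'   columns `codon_index` (1-based slot), `codon` (original), `option`
#'   (candidate codon) and `prob`.
#' @examples
#' p <- gc3_option_probs("ATTATTATTATCGACGACGACGACGACGAC") # GC3 = 0.6
#' subset(p, codon_index == 1) # Ile: ATC 0.6, ATA/ATT 0.2 each
#' @export
gc3_option_probs <- function(seq, freeze_stops = FALSE,
                             gc3_include_fixed = TRUE) {
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops, gc3_include_fixed)
  g <- plan$g
  rows <- lapply(seq_len(plan$n_codons), function(i) {
    cls <- plan$class[i]
    if (cls == "FIXED") {
      return(data.frame(codon_index = i, codon = plan$codons[i],
                        option = plan$codons[i], prob = 1))
    }
    thirds <- CLASS_THIRD_POSITIONS[[cls]]
    is_gc <- thirds %in% c("G", "C")
    prob <- ifelse(is_gc, g / sum(is_gc), (1 - g) / sum(!is_gc))
    data.frame(codon_index = i, codon = plan$codons[i],
               option = paste0(substr(plan$codons[i], 1L, 2L), thirds),
               prob = prob)
  })
  do.call(rbind, rows)
}

#' Per-option dn23 draw probabilities
#'
#' The dn23 rule weights each synonymous option of a codon by the subject's
#' frequency of the (position-2, candidate-position-3) dinucleotide,
#' normalized over that codon's options; if every option has zero frequency
#' (a pathological table) the draw falls back to uniform.
#'
#' @inheritParams gc3_option_probs
#' @return A data frame in the layout of [gc3_option_probs()], with an
#'   additional `weight` column holding the unnormalized dinucleotide
#'   frequency.
#' @export
dn23_option_probs <- function(seq, freeze_stops = FALSE) {
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops)
  rows <- lapply(seq_len(plan$n_codons), function(i) {
    cls <- plan$class[i]
    if (cls == "FIXED") {
      return(data.frame(codon_index = i, codon = plan$codons[i],
                        option = plan$codons[i], weight = 1, prob = 1))
    }
    thirds <- CLASS_THIRD_POSITIONS[[cls]]
    w <- plan$dn_freq[match(paste0(plan$second[i], thirds), plan$dn_names)]
    prob <- if (sum(w) == 0) rep(1 / length(w), length(w)) else w / sum(w)
    data.frame(codon_index = i, codon = plan$codons[i],
               option = paste0(substr(plan$codons[i], 1L, 2L), thirds),
               weight = w, prob = prob)
  })
  do.call(rbind, rows)
}

# Draw new third positions for the mutable codons of a plan, vectorized by
# degeneracy class. Returns a character vector of third positions (FIXED
# slots keep their original base). `n_rep` independent replicates are drawn
# at once; the result is an n_codons x n_rep matrix.
draw_thirds <- function(plan, method, n_rep = 1L) {
  out <- matrix(rep(plan$third, n_rep), nrow = plan$n_codons, ncol = n_rep)
  for (cls in c("R", "Y", "H", "N")) {
    idx <- which(plan$class == cls)
    if (length(idx) == 0L) next
    thirds <- CLASS_THIRD_POSITIONS[[cls]]
    if (method == "gc3") {
      is_gc <- thirds %in% c("G", "C")
      prob <- ifelse(is_gc, plan$g / sum(is_gc), (1 - plan$g) / sum(!is_gc))
      out[idx, ] <- sample(thirds, length(idx) * n_rep, replace = TRUE,
                           prob = prob)
    } else if (method == "n3") {
      for (j in seq_len(n_rep)) {
        out[idx, j] <- plan$third[idx][sample.int(length(idx))]
      }
    } else { # dn23: weights depend on the codon's second base
      for (b in unique(plan$second[idx])) {
        bi <- idx[plan$second[idx] == b]
        w <- plan$dn_freq[match(paste0(b, thirds), plan$dn_names)]
        if (sum(w) == 0) w <- rep(1, length(thirds)) # degenerate: uniform
        out[bi, ] <- sample(thirds, length(bi) * n_rep, replace = TRUE,
                            prob = w)
      }
    }
  }
  out
}

rebuild_sequences <- function(plan, thirds_matrix) {
  prefix <- substr(plan$codons, 1L, 2L)
  apply(thirds_matrix, 2L, function(th) paste(prefix, th, sep = "",
                                              collapse = ""))
}

#' Synonymous shuffles of a coding sequence
#'
#' `gc3_shuffle()`, `n3_shuffle()` and `dn23_shuffle()` each return one
#' shuffled sequence; [generate_null()] returns a replicate set. All three
#' preserve the translation exactly. `n3_shuffle()` additionally preserves
#' the base composition of the whole sequence exactly; `gc3_shuffle()`
#' matches third-position GC content in expectation only, and
#' `dn23_shuffle()` matches positions-2-3 dinucleotide frequencies in
#' expectation.
#'
#' These functions use R's global random number generator; call
#' [set.seed()] (or use [generate_null()]'s `seed` argument) for
#' reproducibility.
#'
#' @inheritParams shuffle_plan
#' @param seq A [coding_sequence()], plain string, or a precomputed
#'   [shuffle_plan()].
#' @return A plain character string (same length as the input).
#' @examples
#' set.seed(1)
#' gc3_shuffle("ATTGAACCATGG")
#' @export
gc3_shuffle <- function(seq, freeze_stops = FALSE, gc3_include_fixed = TRUE) {
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops, gc3_include_fixed)
  rebuild_sequences(plan, draw_thirds(plan, "gc3"))
}

#' @rdname gc3_shuffle
#' @export
n3_shuffle <- function(seq, freeze_stops = FALSE) {
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops)
  rebuild_sequences(plan, draw_thirds(plan, "n3"))
}

#' @rdname gc3_shuffle
#' @export
dn23_shuffle <- function(seq, freeze_stops = FALSE) {
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops)
  rebuild_sequences(plan, draw_thirds(plan, "dn23"))
}

#' Generate the null replicate set
#'
#' Draws `r` independent synonymous shuffles of the subject under the chosen
#' method. Identical `(method, seed, input)` yields a byte-identical
#' replicate stream.
#'
#' @inheritParams shuffle_plan
#' @param method One of `"gc3"`, `"n3"`, `"dn23"`.
#' @param r Number of replicates (the paper-default used throughout this
#'   package is 1000).
#' @param seed Optional integer seed applied before drawing.
#' @return Character vector of `r` shuffled sequences.
#' @examples
#' generate_null("ATTGAACCA", method = "n3", r = 3, seed = 7)
#' @export
generate_null <- function(seq, method = c("gc3", "n3", "dn23"), r = 1000L,
                          seed = NULL, freeze_stops = FALSE,
                          gc3_include_fixed = TRUE) {
  method <- match.arg(method)
  if (!is.numeric(r) || length(r) != 1L || r < 1) {
    stop("'r' must be a positive integer", call. = FALSE)
  }
  r <- as.integer(r)
  if (!is.null(seed)) set.seed(seed)
  plan <- if (inherits(seq, "shuffle_plan")) seq else
    shuffle_plan(seq, freeze_stops, gc3_include_fixed)
  rebuild_sequences(plan, draw_thirds(plan, method, n_rep = r))
}
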