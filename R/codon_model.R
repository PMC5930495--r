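# Genetic-code foundation: translation, third-position degeneracy classes,
# synonymous codon options. Everything downstream (shuffling, replacement-
# transition classification) is built on these tables.

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

# Third-position degeneracy class of each codon, given that codon positions
# 1-2 stay fixed: R = {A,G}, Y = {C,T}, H = {A,C,T}, N = {A,C,G,T},
# FIXED = the original base only (ATG, TGG; TGA cannot leave the stop state
# without becoming Cys/Trp). Six-codon amino acids (Leu, Ser, Arg) split
# naturally into a two-codon and a four-codon family because positions 1-2
# differ between the families. TAA/TAG are mutually synonymous stops (R).
CODON_CLASS <- c(
  AAA = "R", AAC = "Y", AAG = "R", AAT = "Y",
  ACA = "N", ACC = "N", ACG = "N", ACT = "N",
  AGA = "R", AGC = "Y", AGG = "R", AGT = "Y",
  ATA = "H", ATC = "H", ATG = "FIXED", ATT = "H",
  CAA = "R", CAC = "Y", CAG = "R", CAT = "Y",
  CCA = "N", CCC = "N", CCG = "N", CCT = "N",
  CGA = "N", CGC = "N", CGG = "N", CGT = "N",
  CTA = "N", CTC = "N", CTG = "N", CTT = "N",
  GAA = "R", GAC = "Y", GAG = "R", GAT = "Y",
  GCA = "N", GCC = "N", GCG = "N", GCT = "N",
  GGA = "N", GGC = "N", GGG = "N", GGT = "N",
  GTA = "N", GTC = "N", GTG = "N", GTT = "N",
  TAA = "R", TAC = "Y", TAG = "R", TAT = "Y",
  TCA = "N", TCC = "N", TCG = "N", TCT = "N",
  TGA = "FIXED", TGC = "Y", TGG = "FIXED", TGT = "Y",
  TTA = "R", TTC = "Y", TTG = "R", TTT = "Y"
)

CLASS_THIRD_POSITIONS <- list(
  R = c("A", "G"),
  Y = c("C", "T"),
  H = c("A", "C", "T"),
  N = c("A", "C", "G", "T")
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a validated coding sequence
#'
#' A coding sequence is an in-frame CDS over the strict alphabet
#' \{A, C, G, T\}: length a positive multiple of 3, reading frame starting at
#' position 0. Lower-case input is upper-cased and RNA-style `U` is mapped to
#' `T` with a warning; IUPAC ambiguity codes and gaps are rejected because
#' every downstream motif count would be ill-defined on them. Internal stop
#' codons are tolerated with a warning by default (viral ORF annotations
#' sometimes contain them) and rejected under `strict = TRUE`.
#'
#' @param nucleotides Single character string with the nucleotide sequence.
#' @param id Identifier carried into reports (FASTA header, typically).
#' @param strict Reject internal stop codons instead of warning.
#' @return A character scalar of class `coding_sequence` with an `id`
#'   attribute.
#' @examples
#' coding_sequence("ATGTGGTAA", id = "toy")
#' @export
coding_sequence <- function(nucleotides, id = "", strict = FALSE) {
  if (!is.character(nucleotides) || length(nucleotides) != 1L ||
      is.na(nucleotides)) {
    stop("'nucleotides' must be a single character string", call. = FALSE)
  }
  s <- toupper(nucleotides)
  if (grepl("U", s, fixed = TRUE)) {
    warning("RNA-style 'U' bases mapped to 'T' in ", sQuote(id), call. = FALSE)
    s <- gsub("U", "T", s, fixed = TRUE)
  }
  n <- nchar(s)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence ", sQuote(id), " has length ", n,
         ": must be a positive multiple of 3 (in-frame CDS)", call. = FALSE)
  }
  if (grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop("sequence ", sQuote(id), " contains non-ACGT characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  starts <- seq.int(1L, n, by = 3L)
  aa <- unname(GENETIC_CODE_TABLE[substring(s, starts, starts + 2L)])
  internal_stops <- sum(aa[-length(aa)] == "*")
  if (internal_stops > 0L) {
    msg <- paste0("sequence ", sQuote(id), " contains ", internal_stops,
                  " internal stop codon(s)")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(s, class = "coding_sequence", id = id)
}

#' @export
print.coding_sequence <- function(x, ...) {
  n <- nchar(x)
  cat("<coding_sequence> ", attr(x, "id"), ": ", n, " nt (", n %/% 3L,
      " codons)\n", sep = "")
  show <- if (n > 60L) paste0(substr(x, 1L, 57L), "...") else unclass(x)
  cat(" ", show, "\n", sep = "")
  invisible(x)
}

# Cheap coercion used on internal hot paths: validates only when the input
# is not already a coding_sequence.
as_cds_string <- function(seq) {
  if (inherits(seq, "coding_sequence")) return(unclass(seq))
  unclass(coding_sequence(as.character(seq)))
}

split_codons <- function(seq) {
  s <- as_cds_string(seq)
  starts <- seq.int(1L, nchar(s), by = 3L)
  substring(s, starts, starts + 2L)
}

#' Translate an in-frame coding sequence
#'
#' Standard genetic code (NCBI translation table 1); stop codons are rendered
#' as `*`.
#'
#' @param seq A [coding_sequence()] or a plain in-frame ACGT string.
#' @return Single amino-acid string of length `nchar(seq)/3`.
#' @examples
#' translate_cds("ATGTGGTAA") # "MW*"
#' @export
translate_cds <- function(seq) {
  paste(GENETIC_CODE_TABLE[split_codons(seq)], collapse = "")
}

#' Third-position degeneracy class of a codon
#'
#' With codon positions 1-2 held fixed, the synonymous options at position 3
#' fall into one of four classes dictated by the genetic code: `R` (A/G),
#' `Y` (C/T), `H` (A/C/T) or `N` (any base); codons admitting no synonymous
#' change (ATG, TGG, TGA) are `FIXED`. The stop pair TAA/TAG is treated as an
#' interchangeable R-class family; `freeze_stops = TRUE` forces all stop
#' codons to `FIXED` for users who prefer never to touch them.
#'
#' @param codon Character vector of 3-mers over \{A,C,G,T\}.
#' @param freeze_stops Treat TAA/TAG as immutable instead of an R pair.
#' @return Character vector of class labels.
#' @examples
#' classify_codon(c("ATC", "GGA", "ATG", "TTA")) # "H" "N" "FIXED" "R"
#' @export
classify_codon <- function(codon, freeze_stops = FALSE) {
  codon <- toupper(codon)
  bad <- is.na(CODON_CLASS[codon])
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  cls <- unname(CODON_CLASS[codon])
  if (freeze_stops) cls[codon %in% STOP_CODONS] <- "FIXED"
  cls
}

#' Synonymous third-position variants of a codon
#'
#' All codons sharing positions 1-2 with the input and encoding the same
#' amino acid (or remaining a stop). Always contains the input codon.
#'
#' @inheritParams classify_codon
#' @param codon A single 3-mer.
#' @return Character vector of codons, alphabetically ordered.
#' @examples
#' synonymous_options("ATC") # "ATA" "ATC" "ATT"
#' synonymous_options("TGG") # "TGG"
#' @export
synonymous_options <- function(codon, freeze_stops = FALSE) {
  stopifnot(length(codon) == 1L)
  codon <- toupper(codon)
  cls <- classify_codon(codon, freeze_stops = freeze_stops)
  if (cls == "FIXED") return(codon)
  paste0(substr(codon, 1L, 2L), CLASS_THIRD_POSITIONS[[cls]])
}
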