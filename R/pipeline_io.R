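# User-facing shell: FASTA input, motif configuration files, and the
# command-line entry point (exec/cdur wraps cdur_main()).

#' Read coding sequences from a FASTA file
#'
#' Each record is validated as an in-frame CDS (see [coding_sequence()]);
#' validation failures are reported per record, naming the offending header.
#'
#' @param path FASTA file path.
#' @param strict Reject records with internal stop codons.
#' @return List of [coding_sequence()] objects.
#' @export
read_fasta <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    id <- names(set)[i]
    out[[i]] <- tryCatch(
      coding_sequence(as.character(set[[i]]), id = id, strict = strict),
      error = function(e) stop("record ", i, " (", id, "): ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

#' Parse a motif configuration file
#'
#' Plain-text format, one motif per line; `#` starts a comment. Fields are
#' separated by commas and/or whitespace. The first field is the IUPAC
#' pattern (also used as the report name unless overridden); the remaining
#' fields are `key=value` pairs with keys `target` (0-based offset of the
#' deaminated C), `strand`/`strands` (`top`, `bottom`, `both`) and `name`.
#'
#' ```
#' # pattern  options
#' TAC, target=2, strands=both
#' WRC, strand=top
#' CG
#' ```
#'
#' @param path Config file path, or `NULL` for the default vocabulary.
#' @return List of [motif_spec()] objects.
#' @export
parse_motif_config <- function(path = NULL) {
  if (is.null(path)) return(default_motif_set())
  if (!file.exists(path)) {
    stop("motif config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    stop("motif config ", path, " defines no motifs", call. = FALSE)
  }
  lapply(lines, function(line) {
    toks <- strsplit(line, "[,[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    pattern <- toks[1L]
    target <- NULL; strand <- "both"; name <- pattern
    for (tok in toks[-1L]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        stop("malformed config token ", sQuote(tok), " in line ",
             sQuote(line), call. = FALSE)
      }
      key <- tolower(kv[1L])
      if (key == "target") {
        target <- suppressWarnings(as.integer(kv[2L]))
        if (is.na(target)) stop("non-integer target in line ", sQuote(line),
                                call. = FALSE)
      } else if (key %in% c("strand", "strands")) {
        strand <- kv[2L]
        if (!strand %in% c("top", "bottom", "both")) {
          stop("unknown strand ", sQuote(strand), " in line ", sQuote(line),
               call. = FALSE)
        }
      } else if (key == "name") {
        name <- kv[2L]
      } else if (key == "pattern") {
        pattern <- kv[2L]
      } else {
        stop("unknown config key ", sQuote(key), " in line ", sQuote(line),
             call. = FALSE)
      }
    }
    motif_spec(pattern, target_index = target, strand = strand, name = name)
  })
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper around [read_fasta()],
#' [parse_motif_config()], [cdur_report()] and [write_cdur_report()];
#' installed as the `exec/cdur` script. Each FASTA record gets its own
#' report; record `i` (1-based) is analysed with seed `seed + i - 1`, so
#' multi-record runs are order-stable and a single-record run reproduces the
#' equivalent library call.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly: 0 on success, 1 on any
#'   validation, configuration or I/O failure.
#' @export
cdur_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "cdur [options] input.fasta",
    description = "Cytidine deaminase under-representation reporter",
    option_list = list(
      optparse::make_option("--shuffle", default = "gc3",
        help = "null model: gc3, n3 or dn23 [default %default]"),
      optparse::make_option(c("-r", "--replicates"), type = "integer",
        default = 1000L, help = "shuffle replicates [default %default]"),
      optparse::make_option("--seed", type = "integer", default = 42L,
        help = "random seed [default %default]"),
      optparse::make_option("--motifs", default = NULL,
        help = "motif configuration file (default: built-in 23-motif set)"),
      optparse::make_option("--threshold", type = "double", default = 0.05,
        help = "significance threshold q [default %default]"),
      optparse::make_option("--out", default = "cdur_report",
        help = "output path stem [default %default]"),
      optparse::make_option("--format", default = "kv",
        help = "output format: kv or tsv [default %default]"),
      optparse::make_option("--no-bivariate", action = "store_true",
        dest = "no_bivariate", default = FALSE,
        help = "skip pairwise correlation / conditional statistics"),
      optparse::make_option("--strict", action = "store_true",
        default = FALSE, help = "reject sequences with internal stops"),
      optparse::make_option("--verbose", action = "store_true",
        default = FALSE, help = "log progress to stderr")
    ))
  status <- tryCatch({
    parsed <- optparse::parse_args(parser, args = args,
                                   positional_arguments = TRUE)
    opt <- parsed$options
    if (length(parsed$args) != 1L) {
      stop("exactly one input FASTA path is required", call. = FALSE)
    }
    if (!opt$shuffle %in% SHUFFLE_METHODS) {
      stop("unknown shuffle method ", sQuote(opt$shuffle), call. = FALSE)
    }
    if (!opt$format %in% c("kv", "tsv")) {
      stop("unknown output format ", sQuote(opt$format), call. = FALSE)
    }
    log_msg <- function(...) if (opt$verbose) message("[cdur] ", ...)
    motifs <- parse_motif_config(opt$motifs)
    seqs <- read_fasta(parsed$args, strict = opt$strict)
    log_msg("method=", opt$shuffle, " r=", opt$replicates,
            " seed=", opt$seed, " motifs=", length(motifs),
            " records=", length(seqs))
    ext <- if (opt$format == "tsv") ".tsv" else ".txt"
    for (i in seq_along(seqs)) {
      t0 <- proc.time()[["elapsed"]]
      rep <- cdur_report(seqs[[i]], method = opt$shuffle,
                         r = opt$replicates, seed = opt$seed + i - 1L,
                         motifs = motifs, q = opt$threshold,
                         bivariate = !opt$no_bivariate)
      out_path <- if (length(seqs) == 1L) paste0(opt$out, ext) else
        paste0(opt$out, "_record", i, ext)
      write_cdur_report(rep, out_path, format = opt$format)
      log_msg("record ", i, " (", attr(seqs[[i]], "id"), "): ",
              sprintf("%.2fs", proc.time()[["elapsed"]] - t0),
              " -> ", out_path)
    }
    0L
  }, error = function(e) {
    message("cdur: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
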