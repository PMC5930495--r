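# Report flattening and serialization. The canonical output is an ordered
# list of keyword/value pairs whose names follow the established CDUR
# convention: observedTAC, repTr_observedTAC, repTrFrac_observedTAC,
# expectedTAC, expectedSdTAC, belowTAC, corTACxWRC, pTACcondWRC, ...

#' Flatten a report to its ordered keyword/value pairs
#'
#' For every motif X the twelve univariate keys are emitted
#' (`observedX`, `repTr_observedX`, `repTrFrac_observedX`, `expectedX`,
#' `repTr_expectedX`, `repTrFrac_expectedX`, `expectedSdX`,
#' `repTr_expectedSdX`, `repTrFrac_expectedSdX`, `belowX`, `repTr_belowX`,
#' `repTrFrac_belowX`), followed for every motif pair X, Y by the
#' correlation keys (`corXxY`, `corRepTrXxY`, `corRepTrFracXxY`) and both
#' orderings of the conditional p-value keys (`pXcondY`, `pXcondRepTrY`,
#' `pXcondRepTrFracY`, and the Y-given-X triple).
#'
#' @param report A [cdur_report()].
#' @return Named numeric vector.
#' @export
report_values <- function(report) {
  stopifnot(inherits(report, "cdur_report"))
  u <- report$univariate
  out <- numeric(0)
  for (i in seq_len(nrow(u))) {
    X <- u$motif[i]
    v <- c(u$observed[i], u$repTr_observed[i], u$repTrFrac_observed[i],
           u$expected[i], u$repTr_expected[i], u$repTrFrac_expected[i],
           u$expectedSd[i], u$repTr_expectedSd[i], u$repTrFrac_expectedSd[i],
           u$below[i], u$repTr_below[i], u$repTrFrac_below[i])
    names(v) <- c(
      paste0(family_prefix, "observed", X),
      paste0(family_prefix, "expected", X),
      paste0(family_prefix, "expectedSd", X),
      paste0(family_prefix, "below", X)
    )
    out <- c(out, v)
  }
  p <- report$pairs
  if (!is.null(p)) {
    for (i in seq_len(nrow(p))) {
      X <- p$x[i]; Y <- p$y[i]
      v <- c(p$cor_count[i], p$cor_rep_tr[i], p$cor_rep_tr_frac[i],
             p$p_x_cond_y_count[i], p$p_x_cond_y_rep_tr[i],
             p$p_x_cond_y_rep_tr_frac[i],
             p$p_y_cond_x_count[i], p$p_y_cond_x_rep_tr[i],
             p$p_y_cond_x_rep_tr_frac[i])
      names(v) <- c(
        paste0("cor", family_infix, X, "x", Y),
        paste0("p", X, "cond", family_infix, Y),
        paste0("p", Y, "cond", family_infix, X)
      )
      out <- c(out, v)
    }
  }
  out
}

#' Write a report to disk
#'
#' `kv` format writes one `key<TAB>value` line per statistic with values
#' shown at 3 significant digits (the conventional display precision),
#' preceded by `#`-prefixed metadata lines. `tsv` writes a two-column table
#' with full double precision, suitable for lossless round-tripping via
#' [read_cdur_report()].
#'
#' @param report A [cdur_report()].
#' @param path Output file path (or `""` for stdout).
#' @param format `"kv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_cdur_report <- function(report, path, format = c("kv", "tsv")) {
  format <- match.arg(format)
  vals <- report_values(report)
  m <- report$meta
  meta_lines <- sprintf("#%s\t%s",
                        c("id", "method", "r", "seed",
                          "significance_threshold"),
                        c(m$id, m$method, m$r, m$seed,
                          m$significance_threshold))
  fmt <- if (format == "kv") function(x) trimws(formatC(x, digits = 3L,
                                                        format = "g")) else
    function(x) format(x, digits = 17L, scientific = FALSE, trim = TRUE)
  lines <- c(if (format == "kv") meta_lines,
             if (format == "tsv") "key\tvalue",
             sprintf("%s\t%s", names(vals), vapply(vals, fmt, character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Read back a serialized report
#'
#' @param path File written by [write_cdur_report()].
#' @return Named numeric vector of the report's statistics (metadata and
#'   header lines are skipped).
#' @export
read_cdur_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[[`, character(1), 1L)
  raw <- vapply(parts, `[[`, character(1), 2L)
  if (length(keys) && keys[1L] == "key") {
    keys <- keys[-1L]; raw <- raw[-1L]
  }
  stats::setNames(suppressWarnings(as.numeric(raw)), keys)
}

#' @export
as.data.frame.cdur_report <- function(x, ...) {
  vals <- report_values(x)
  data.frame(key = names(vals), value = unname(vals))
}
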