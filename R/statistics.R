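# Statistical reporter: empirical under-representation p-values against the
# shuffle null, null-distribution summaries, pairwise motif correlations and
# bivariate-normal conditional p-values.

#' Empirical lower-tail p-value against a null vector
#'
#' The fraction of null replicates with a value strictly less than the
#' observed one — the empirical estimate of the under-representation
#' p-value. Missing null entries (replicates where a ratio was 0/0) are
#' dropped. The strict "less than" rule is the reporting default; for
#' discrete counts at small replicate numbers it is anti-conservative, so a
#' mid-p variant that counts ties at half weight is available.
#'
#' @param null_values Numeric vector of null replicate values.
#' @param observed Observed subject value.
#' @param midp Count ties at half weight instead of ignoring them.
#' @return p-value in \[0, 1\], or `NA` (with a warning) when every null
#'   entry is missing.
#' @examples
#' empirical_below(c(1, 2, 3, 4), 3) # 0.5
#' @export
empirical_below <- function(null_values, observed, midp = FALSE) {
  v <- null_values[!is.na(null_values)]
  if (length(v) == 0L) {
    warning("all null values missing; p-value undefined", call. = FALSE)
    return(NA_real_)
  }
  if (is.na(observed)) return(NA_real_)
  if (midp) {
    (sum(v < observed) + 0.5 * sum(v == observed)) / length(v)
  } else {
    sum(v < observed) / length(v)
  }
}

#' Classify a p-value as under-, over-represented or neutral
#'
#' A motif metric is called under-represented when its empirical p-value
#' falls below the threshold `q` and over-represented when it exceeds
#' `1 - q`.
#'
#' @param p p-value(s) in \[0, 1\].
#' @param q Significance threshold in (0, 0.5); 0.05 by convention.
#' @return Character vector over `"under"`, `"over"`, `"neutral"` (`NA` for
#'   missing p-values).
#' @examples
#' classify_representation(c(0.008, 0.36, 0.96)) # under, neutral, over
#' @export
classify_representation <- function(p, q = 0.05) {
  stopifnot(q > 0, q < 0.5)
  ifelse(is.na(p), NA_character_,
         ifelse(p < q, "under", ifelse(p > 1 - q, "over", "neutral")))
}

#' Pearson correlation between two null replicate vectors
#'
#' Replicates where either entry is missing are dropped pairwise; a
#' zero-variance vector yields `NA` rather than an error, since a constant
#' null carries no correlation information.
#'
#' @param x,y Numeric vectors of equal length (one entry per replicate).
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
pairwise_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Bivariate-normal conditional p-value
#'
#' Approximates the joint null of two motif metrics by a bivariate normal
#' with the null means, SDs and correlation, and returns the lower-tail
#' probability of the observed X under the conditional law of X given
#' Y = observed Y: normal with mean
#' `mean_x + rho * (sd_x / sd_y) * (obs_y - mean_y)` and SD
#' `sd_x * sqrt(1 - rho^2)`.
#'
#' @param obs_x,obs_y Observed subject values of the two metrics.
#' @param mean_x,mean_y,sd_x,sd_y Null means and standard deviations.
#' @param rho Null correlation between the metrics, in (-1, 1).
#' @return Conditional p-value in \[0, 1\]; `NA` (with a warning) in
#'   degenerate cases (`rho = +-1`, zero SD, missing inputs).
#' @examples
#' conditional_pvalue(11, 12, 10, 10, 2, 2, 0.5) # conditional mean 11 -> 0.5
#' @export
conditional_pvalue <- function(obs_x, obs_y, mean_x, mean_y, sd_x, sd_y,
                               rho) {
  if (anyNA(c(obs_x, obs_y, mean_x, mean_y, sd_x, sd_y, rho))) {
    return(NA_real_)
  }
  if (sd_x <= 0 || sd_y <= 0 || abs(rho) >= 1) {
    warning("degenerate conditional distribution; p-value undefined",
            call. = FALSE)
    return(NA_real_)
  }
  mu <- mean_x + rho * (sd_x / sd_y) * (obs_y - mean_y)
  sigma <- sd_x * sqrt(1 - rho^2)
  stats::pnorm(obs_x, mean = mu, sd = sigma)
}

metric_families <- c(count = "count", rep_tr = "rep_tr",
                     rep_tr_frac = "rep_tr_frac")

# Key-name fragments per metric family, following the report's naming
# convention: belowX / repTr_belowX / repTrFrac_belowX and so on.
family_prefix <- c(count = "", rep_tr = "repTr_", rep_tr_frac = "repTrFrac_")
family_infix <- c(count = "", rep_tr = "RepTr", rep_tr_frac = "RepTrFrac")

#' Run the full under-/over-representation analysis
#'
#' Generates `r` synonymous shuffles of the subject under the chosen method,
#' measures every motif's occurrence count, replacement-transition count and
#' replacement-transition fraction on the subject and on each replicate, and
#' assembles all univariate statistics (observed, null mean/SD, empirical
#' under-representation p-value) plus, optionally, all pairwise bivariate
#' statistics (null correlations and bivariate-normal conditional p-values,
#' per metric family).
#'
#' @inheritParams generate_null
#' @param motifs List of [motif_spec()] objects; defaults to the 23-motif
#'   vocabulary of [default_motif_set()].
#' @param q Significance threshold used by the printed classification.
#' @param bivariate Compute pairwise correlations and conditional p-values
#'   (quadratic in the number of motifs).
#' @param midp Use mid-p tie handling in empirical p-values (see
#'   [empirical_below()]).
#' @return An object of class `cdur_report`: a list with `meta` (method, r,
#'   seed, q), `univariate` (data frame, one row per motif), `pairs` (data
#'   frame, one row per ordered motif pair, `NULL` when `bivariate = FALSE`)
#'   and `null` (per-motif replicate metric data frames, kept so that
#'   summaries can be audited).
#' @examples
#' rep <- cdur_report("ATGACTACTACGACGTGGTAA", r = 50, seed = 1,
#'                    motifs = list(motif_spec("TAC")), bivariate = FALSE)
#' rep$univariate
#' @export
cdur_report <- function(seq, method = c("gc3", "n3", "dn23"), r = 1000L,
                        seed = NULL, motifs = default_motif_set(),
                        q = 0.05, bivariate = TRUE, midp = FALSE,
                        freeze_stops = FALSE, gc3_include_fixed = TRUE) {
  method <- match.arg(method)
  stopifnot(q > 0, q < 0.5)
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  if (length(motifs) == 0L) stop("no motifs configured", call. = FALSE)
  names(motifs) <- vapply(motifs, `[[`, character(1), "name")
  if (anyDuplicated(names(motifs))) {
    stop("duplicate motif names in configuration", call. = FALSE)
  }
  s <- as_cds_string(seq)
  null_seqs <- generate_null(s, method = method, r = r, seed = seed,
                             freeze_stops = freeze_stops,
                             gc3_include_fixed = gc3_include_fixed)

  null <- lapply(motifs, function(m) metrics_for_set(null_seqs, m))
  obs <- lapply(motifs, function(m) metrics_for_set(s, m))

  uni <- do.call(rbind, lapply(names(motifs), function(nm) {
    nd <- null[[nm]]
    ob <- obs[[nm]]
    n_dropped <- sum(is.na(nd$rep_tr_frac))
    if (n_dropped > 0L) {
      message(n_dropped, " of ", nrow(nd), " replicates had zero ", nm,
              " occurrences; dropped from the fraction null")
    }
    data.frame(
      motif = nm,
      observed = ob$count, repTr_observed = ob$rep_tr,
      repTrFrac_observed = ob$rep_tr_frac,
      expected = mean(nd$count), repTr_expected = mean(nd$rep_tr),
      repTrFrac_expected = mean(nd$rep_tr_frac, na.rm = TRUE),
      expectedSd = stats::sd(nd$count),
      repTr_expectedSd = stats::sd(nd$rep_tr),
      repTrFrac_expectedSd = stats::sd(nd$rep_tr_frac[!is.na(nd$rep_tr_frac)]),
      below = empirical_below(nd$count, ob$count, midp),
      repTr_below = empirical_below(nd$rep_tr, ob$rep_tr, midp),
      repTrFrac_below = empirical_below(nd$rep_tr_frac, ob$rep_tr_frac, midp)
    )
  }))
  rownames(uni) <- NULL

  pairs <- NULL
  if (bivariate && length(motifs) >= 2L) {
    nm <- names(motifs)
    combos <- utils::combn(nm, 2L)
    rows <- lapply(seq_len(ncol(combos)), function(k) {
      x <- combos[1L, k]; y <- combos[2L, k]
      row <- data.frame(x = x, y = y)
      for (fam in metric_families) {
        rho <- pairwise_correlation(null[[x]][[fam]], null[[y]][[fam]])
        row[[paste0("cor_", fam)]] <- rho
        row[[paste0("p_x_cond_y_", fam)]] <- conditional_pvalue(
          obs[[x]][[fam]], obs[[y]][[fam]],
          mean(null[[x]][[fam]], na.rm = TRUE),
          mean(null[[y]][[fam]], na.rm = TRUE),
          stats::sd(null[[x]][[fam]][!is.na(null[[x]][[fam]])]),
          stats::sd(null[[y]][[fam]][!is.na(null[[y]][[fam]])]), rho)
        row[[paste0("p_y_cond_x_", fam)]] <- conditional_pvalue(
          obs[[y]][[fam]], obs[[x]][[fam]],
          mean(null[[y]][[fam]], na.rm = TRUE),
          mean(null[[x]][[fam]], na.rm = TRUE),
          stats::sd(null[[y]][[fam]][!is.na(null[[y]][[fam]])]),
          stats::sd(null[[x]][[fam]][!is.na(null[[x]][[fam]])]), rho)
      }
      row
    })
    pairs <- do.call(rbind, rows)
  }

  structure(list(
    meta = list(id = if (inherits(seq, "coding_sequence"))
                  attr(seq, "id") else "",
                method = method, r = as.integer(r),
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                significance_threshold = q, midp = midp,
                n_codons = nchar(s) %/% 3L),
    univariate = uni, pairs = pairs, null = null
  ), class = "cdur_report")
}

#' Benjamini-Hochberg adjustment of the under-representation p-values
#'
#' A convenience layered on top of the report: the analysis itself emits raw
#' empirical p-values only, but when all 23 default motifs are scanned a
#' false-discovery-rate view is often wanted. Note that the `below` values
#' are lower-tail empirical probabilities, not two-sided test p-values, so
#' the adjustment is meaningful only for the under-representation direction.
#'
#' @param report A [cdur_report()].
#' @return Data frame with motif, raw `below` values per family and their
#'   BH-adjusted counterparts.
#' @export
bh_adjusted_below <- function(report) {
  stopifnot(inherits(report, "cdur_report"))
  u <- report$univariate
  data.frame(
    motif = u$motif,
    below = u$below, below_bh = stats::p.adjust(u$below, "BH"),
    repTr_below = u$repTr_below,
    repTr_below_bh = stats::p.adjust(u$repTr_below, "BH"),
    repTrFrac_below = u$repTrFrac_below,
    repTrFrac_below_bh = stats::p.adjust(u$repTrFrac_below, "BH")
  )
}

#' @export
print.cdur_report <- function(x, ...) {
  m <- x$meta
  cat("CDUR report", if (nzchar(m$id)) paste0(" for ", sQuote(m$id)),
      "\n", sep = "")
  cat("  method=", m$method, "  r=", m$r, "  seed=",
      ifelse(is.na(m$seed), "none", m$seed), "  q=",
      m$significance_threshold, "  codons=", m$n_codons, "\n", sep = "")
  u <- x$univariate
  cls <- classify_representation(u$below, m$significance_threshold)
  flagged <- which(!is.na(cls) & cls != "neutral")
  cat("  motifs analysed: ", nrow(u), "; non-neutral motif counts: ",
      length(flagged), "\n", sep = "")
  if (length(flagged)) {
    for (i in flagged) {
      cat(sprintf("    %-5s below=%.3g (%s; observed %d, expected %.1f)\n",
                  u$motif[i], u$below[i], cls[i], u$observed[i],
                  u$expected[i]))
    }
  }
  invisible(x)
}
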