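# Per-measurement two-sample tests over the seven group contrasts of the
# five-group study design.

#' Two-sample test on a measurement
#'
#' Two-sided p-value of the t statistic comparing two groups of values.
#' The default is Welch's unequal-variance test, appropriate for the
#' unequal, unpaired group sizes of the study design; Student's pooled test
#' and a paired test are selectable.  Non-finite values are dropped.  If
#' both groups have zero variance the p-value is 1 when the means agree and
#' 0 otherwise (the degenerate limit of the t statistic).
#'
#' @param a,b Numeric vectors with at least 2 finite values each.
#' @param mode One of `"welch"` (default), `"student"`, `"paired"`; paired
#'   requires equal lengths.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
#' @examples
#' two_sample_test(c(1, 2, 3), c(1, 2, 3))  # identical groups: p = 1
two_sample_test <- function(a, b, mode = c("welch", "student", "paired")) {
  mode <- match.arg(mode)
  if (mode == "paired" && length(a) != length(b))
    stop("paired test requires equal group lengths")
  if (mode == "paired") {
    keep <- is.finite(a) & is.finite(b)
    a <- a[keep]; b <- b[keep]
  } else {
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  if (mode == "paired") {
    d <- a - b
    if (var(d) == 0) return(if (mean(d) == 0) 1 else 0)
    return(t.test(a, b, paired = TRUE)$p.value)
  }
  if (var(a) == 0 && var(b) == 0)
    return(if (mean(a) == mean(b)) 1 else 0)
  t.test(a, b, var.equal = (mode == "student"))$p.value
}

# the seven contrasts: each entry gives the two pooled group sets
study_contrasts <- function() {
  list(
    "Control v Patient" = list(
      "control",
      c("pre-successful", "pre-unsuccessful", "post-successful",
        "post-unsuccessful")),
    "Pre- v Post-" = list(
      c("pre-successful", "pre-unsuccessful"),
      c("post-successful", "post-unsuccessful")),
    "Successful v Unsuccessful" = list(
      c("pre-successful", "post-successful"),
      c("pre-unsuccessful", "post-unsuccessful")),
    "Pre-Successful v Pre-Unsuccessful" = list(
      "pre-successful", "pre-unsuccessful"),
    "Post-Successful v Post-Unsuccessful" = list(
      "post-successful", "post-unsuccessful"),
    "Pre-Successful v Post-Successful" = list(
      "pre-successful", "post-successful"),
    "Pre-Unsuccessful v Post-Unsuccessful" = list(
      "pre-unsuccessful", "post-unsuccessful"))
}

#' Compare measurement distributions across the study groups
#'
#' For each of the 32 measurements, computes the p-value of
#' [two_sample_test()] for the seven study contrasts: control vs patient
#' (all four fracture groups pooled), pre vs post, successful vs
#' unsuccessful, and the four pairwise contrasts within and across the
#' outcome/time split.  Contrasts with fewer than 2 finite values in either
#' pooled group yield `NA` rather than an error.  No multiple-testing
#' correction is applied; p-values below `alpha` are flagged in the
#' `significant` attribute (and marked by [print()]), with an optional
#' Benjamini-Hochberg adjusted table available via `adjust`.
#'
#' @param table Data frame with columns `case_id`, `group` and the 32
#'   measurement columns (see [measurement_names()]), e.g. from
#'   [run_study()] or [generate_cohort()].
#' @param mode Test mode passed to [two_sample_test()].
#' @param alpha Significance level for flagging (default 0.05).
#' @param adjust If `TRUE`, attach a Benjamini-Hochberg adjusted p-value
#'   matrix as attribute `"p_adjusted"`.
#' @return Data frame of class `comparison_table`: columns `measurement`,
#'   `landmark` and the seven contrast p-value columns; logical attribute
#'   matrix `"significant"`.
#' @export
compare_groups <- function(table, mode = "welch", alpha = 0.05,
                           adjust = FALSE) {
  stopifnot(is.data.frame(table))
  need <- c("group", measurement_names())
  missing <- setdiff(need, names(table))
  if (length(missing) > 0)
    stop(sprintf("study table is missing column(s): %s",
                 paste(missing, collapse = ", ")))
  bad <- setdiff(unique(table$group), study_groups())
  if (length(bad) > 0)
    stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")))
  contrasts <- study_contrasts()
  meas <- measurement_names()
  pmat <- matrix(NA_real_, length(meas), length(contrasts),
                 dimnames = list(meas, names(contrasts)))
  n_dropped <- 0L
  for (m in meas) {
    v <- table[[m]]
    n_dropped <- n_dropped + sum(!is.finite(v))
    for (ct in names(contrasts)) {
      ga <- v[table$group %in% contrasts[[ct]][[1]]]
      gb <- v[table$group %in% contrasts[[ct]][[2]]]
      ga <- ga[is.finite(ga)]; gb <- gb[is.finite(gb)]
      if (length(ga) >= 2L && length(gb) >= 2L)
        pmat[m, ct] <- two_sample_test(ga, gb, mode = mode)
    }
  }
  if (n_dropped > 0L)
    message(sprintf("compare_groups: dropped %d non-finite measurement value(s) pairwise",
                    n_dropped))
  out <- data.frame(measurement = meas,
                    landmark = unname(measurement_landmarks()),
                    pmat, check.names = FALSE, row.names = NULL)
  attr(out, "significant") <- !is.na(pmat) & pmat < alpha
  attr(out, "alpha") <- alpha
  if (adjust) {
    padj <- matrix(stats::p.adjust(pmat, method = "BH"), nrow(pmat),
                   ncol(pmat), dimnames = dimnames(pmat))
    attr(out, "p_adjusted") <- padj
  }
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' @export
print.comparison_table <- function(x, ...) {
  sig <- attr(x, "significant")
  y <- as.data.frame(x)
  for (ct in colnames(sig)) {
    y[[ct]] <- ifelse(is.na(x[[ct]]), "NA",
                      paste0(formatC(x[[ct]], format = "f", digits = 3),
                             ifelse(sig[, ct], "*", "")))
  }
  cat(sprintf("Group comparison table (32 measurements x %d contrasts; * = p < %g)\n",
              ncol(sig), attr(x, "alpha")))
  print(y, right = TRUE)
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' Mirrors the study's summary table: measurement name, landmark family,
#' then the seven p-value columns, followed by logical significance flags.
#'
#' @param comparison A `comparison_table` from [compare_groups()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "comparison_table"))
  sig <- attr(comparison, "significant")
  flags <- as.data.frame(sig)
  names(flags) <- paste0(names(flags), " [sig]")
  write.csv(cbind(as.data.frame(comparison), flags), path, row.names = FALSE)
  invisible(path)
}
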