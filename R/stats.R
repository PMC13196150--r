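#' Two-group comparison by unpaired Student's t test
#'
#' Classical equal-variance two-sample t test (the unequal-variance Welch
#' form is available via \code{welch = TRUE}), two-sided, with per-group
#' mean and standard error of the mean (sd / sqrt(n)). Significance stars
#' follow the 0.05 / 0.01 / 0.001 convention.
#'
#' @param valuesA,valuesB numeric samples, each of size >= 2.
#' @param labels length-2 character group names.
#' @param welch use the Welch (unequal-variance) form.
#' @return A \linkS4class{GroupComparison}.
#' @examples
#' compareGroups(rnorm(10), rnorm(10, mean = 2))
#' @export
compareGroups <- function(valuesA, valuesB, labels = c("A", "B"),
                          welch = FALSE) {
  for (v in list(valuesA, valuesB)) {
    if (length(v) < 2 || !all(is.finite(v)))
      stop("each group needs >= 2 finite values", call. = FALSE)
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = !welch)
  p <- tt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  new("GroupComparison", labels = as.character(labels),
      n = c(length(valuesA), length(valuesB)),
      groupMean = c(mean(valuesA), mean(valuesB)),
      groupSem = c(sd(valuesA) / sqrt(length(valuesA)),
                   sd(valuesB) / sqrt(length(valuesB))),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      pValue = p, stars = stars, welch = welch)
}

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s t test):\n",
              if (object@welch) "Welch" else "Student"))
  for (i in 1:2)
    cat(sprintf("  %s: n = %d, mean +/- SEM = %.4g +/- %.4g\n",
                object@labels[i], object@n[i], object@groupMean[i],
                object@groupSem[i]))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n", object@statistic,
              object@df, object@pValue, object@stars))
})
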