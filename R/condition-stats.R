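#' Per-condition summary statistics of aggregate morphometrics
#'
#' Groups per-aggregate records by (surface, incubation time) and reports
#' mean, standard error of the mean (sample standard deviation over
#' \eqn{\sqrt{n}}; 0 when \eqn{n = 1}) and count for each metric. Output is
#' long-format and plot ready.
#'
#' @param records data.frame with columns \code{surface},
#'   \code{timeMin} (> 0) and one column per metric; by default the metrics
#'   are \code{volumeNm3}, \code{boundaryNm}, \code{spreadingPerNm2} (any
#'   subset present is summarized).
#' @param metrics character vector of metric column names to summarize.
#' @return data.frame with columns \code{surface}, \code{timeMin},
#'   \code{metric}, \code{mean}, \code{sem}, \code{n}.
#' @export
summarizeConditions <- function(records,
                                metrics = c("volumeNm3", "boundaryNm",
                                            "spreadingPerNm2")) {
  if (is.null(records) || nrow(records) == 0L) stopf("no records to summarize")
  if (!all(c("surface", "timeMin") %in% names(records)))
    stopf("records must have 'surface' and 'timeMin' columns")
  if (any(records$timeMin <= 0)) stopf("incubation times must be positive")
  metrics <- intersect(metrics, names(records))
  if (length(metrics) == 0L) stopf("no metric columns found")
  out <- list()
  grp <- interaction(records$surface, records$timeMin, drop = TRUE)
  for (met in metrics) {
    for (g in levels(grp)) {
      v <- records[[met]][grp == g]
      first <- which(grp == g)[1]
      out[[length(out) + 1L]] <- data.frame(
        surface = as.character(records$surface[first]),
        timeMin = records$timeMin[first],
        metric = met,
        mean = mean(v),
        sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else 0,
        n = length(v))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$metric, res$surface, res$timeMin), , drop = FALSE]
}

#' Ratio of condition means with propagated error
#'
#' Ratio of the mean of one surface condition to another at a fixed
#' incubation time, with a first-order (delta method) standard error:
#' \eqn{\mathrm{se} = R \sqrt{(s_A/m_A)^2 + (s_B/m_B)^2}}.
#'
#' @param summaries data.frame from \code{\link{summarizeConditions}}.
#' @param metric metric name.
#' @param timeMin incubation time (minutes).
#' @param numeratorSurface,denominatorSurface surface labels.
#' @return list with \code{ratio} and \code{se}.
#' @export
conditionRatio <- function(summaries, metric, timeMin, numeratorSurface,
                           denominatorSurface) {
  pick <- function(surf) {
    r <- summaries[summaries$metric == metric & summaries$timeMin == timeMin &
                   summaries$surface == surf, , drop = FALSE]
    if (nrow(r) != 1L)
      stopf("condition (%s, %s min, %s) not found", surf, timeMin, metric)
    r
  }
  a <- pick(numeratorSurface)
  b <- pick(denominatorSurface)
  ratio <- a$mean / b$mean
  se <- abs(ratio) * sqrt((a$sem / a$mean)^2 + (b$sem / b$mean)^2)
  list(ratio = ratio, se = se)
}

#' Detect a morphological transition in a time course
#'
#' Finds the consecutive pair of incubation times with the largest increase
#' of the condition mean and flags it as a transition when the jump exceeds
#' \code{factor} times the pooled SEM of the two time points
#' (\eqn{\sqrt{s_i^2 + s_{i+1}^2}}). A visual "rapid increase" becomes a
#' stated, reproducible rule this way.
#'
#' @param summaries data.frame from \code{\link{summarizeConditions}}.
#' @param metric metric name.
#' @param surface surface label.
#' @param factor significance multiple of the pooled SEM (default 2).
#' @return list with \code{detected}, and when detected \code{from},
#'   \code{to} (minutes), \code{jump}, \code{pooledSem}.
#' @export
detectTransition <- function(summaries, metric, surface, factor = 2) {
  s <- summaries[summaries$metric == metric & summaries$surface == surface, ,
                 drop = FALSE]
  s <- s[order(s$timeMin), , drop = FALSE]
  if (nrow(s) < 3L) stopf("need at least 3 time points, got %d", nrow(s))
  jumps <- diff(s$mean)
  pooled <- sqrt(s$sem[-nrow(s)]^2 + s$sem[-1]^2)
  k <- which.max(jumps)
  if (jumps[k] > factor * pooled[k])
    list(detected = TRUE, from = s$timeMin[k], to = s$timeMin[k + 1L],
         jump = jumps[k], pooledSem = pooled[k])
  else list(detected = FALSE)
}
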