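#' Kaplan-Meier product-limit estimate
#'
#' Direct implementation of the product-limit estimator
#' \eqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}, per group.
#'
#' @param table data.frame with columns \code{time}, \code{event} and
#'   optionally \code{group} (a single group is assumed otherwise).
#' @return data.frame with columns group, time, nRisk, nEvent, survival,
#'   one row per distinct event time per group.
#' @examples
#' kmEstimate(data.frame(time = c(1, 2, 3), event = 1))$survival
#' @export
kmEstimate <- function(table) {
  table <- .checkSurvivalTable(table)
  out <- lapply(split(table, table$group), function(tb) {
    times <- sort(unique(tb$time[tb$event == 1]))
    if (!length(times))
      return(NULL)
    surv <- 1
    rows <- lapply(times, function(tt) {
      nRisk <- sum(tb$time >= tt)
      nEvent <- sum(tb$time == tt & tb$event == 1)
      surv <<- surv * (1 - nEvent / nRisk)
      data.frame(group = tb$group[1], time = tt, nRisk = nRisk,
                 nEvent = nEvent, survival = surv,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    stop("degenerate survival data: no events observed")
  rownames(out) <- NULL
  out
}

#' Log-rank test
#'
#' Standard observed-minus-expected statistic: at every event time the
#' expected events per group follow the hypergeometric distribution of the
#' risk sets; the chi-square statistic uses the first g - 1 groups and the
#' hypergeometric covariance, with g - 1 degrees of freedom.
#'
#' @param table data.frame with columns time, event, group (>= 2 groups,
#'   >= 1 event per group).
#' @return list with \code{chisq}, \code{df}, \code{p}, and the per-group
#'   observed/expected table.
#' @export
logrankTest <- function(table) {
  table <- .checkSurvivalTable(table)
  grp <- sort(unique(table$group))
  g <- length(grp)
  if (g < 2)
    stop("log-rank needs at least 2 groups")
  ev <- tapply(table$event, table$group, sum)
  if (any(ev == 0))
    stop("degenerate survival data: a group has no events")
  times <- sort(unique(table$time[table$event == 1]))
  O <- stats::setNames(numeric(g), grp)
  E <- stats::setNames(numeric(g), grp)
  V <- matrix(0, g, g, dimnames = list(grp, grp))
  for (tt in times) {
    atRisk <- table$time >= tt
    n <- sum(atRisk)
    d <- sum(table$time == tt & table$event == 1)
    nj <- vapply(grp, function(gg) sum(atRisk & table$group == gg),
                 numeric(1))
    dj <- vapply(grp, function(gg)
      sum(table$time == tt & table$event == 1 & table$group == gg),
      numeric(1))
    O <- O + dj
    E <- E + d * nj / n
    if (n > 1) {
      # hypergeometric covariance of event counts at this time
      V <- V + (d * (n - d) / (n - 1)) *
        (diag(nj / n, g) - tcrossprod(nj / n))
    }
  }
  u <- (O - E)[-g]
  vv <- V[-g, -g, drop = FALSE]
  chisq <- if (all(abs(u) < 1e-12)) 0
           else as.numeric(t(u) %*% solve(vv, u))
  list(chisq = chisq, df = g - 1,
       p = stats::pchisq(chisq, df = g - 1, lower.tail = FALSE),
       table = data.frame(group = grp, observed = as.numeric(O),
                          expected = as.numeric(E)))
}

#' Cox proportional-hazards ratio for two groups
#'
#' Partial-likelihood fit via the survival package; the hazard ratio is
#' exp(coefficient) of the second group level versus the first, with a Wald
#' 95% confidence interval.
#'
#' @param table data.frame with columns time, event, group (exactly 2
#'   groups).
#' @param reference optional reference group level.
#' @return list with \code{hr}, \code{ciLower}, \code{ciUpper}, \code{p}.
#' @export
coxHR <- function(table, reference = NULL) {
  table <- .checkSurvivalTable(table)
  grp <- factor(table$group)
  if (nlevels(grp) != 2)
    stop("hazard ratio requires exactly 2 groups")
  if (!is.null(reference))
    grp <- stats::relevel(grp, ref = reference)
  fit <- survival::coxph(
    survival::Surv(table$time, table$event) ~ grp)
  s <- summary(fit)
  list(hr = unname(s$conf.int[1, "exp(coef)"]),
       ciLower = unname(s$conf.int[1, "lower .95"]),
       ciUpper = unname(s$conf.int[1, "upper .95"]),
       p = unname(s$coefficients[1, "Pr(>|z|)"]))
}

.checkSurvivalTable <- function(table) {
  if (!all(c("time", "event") %in% names(table)))
    stop("survival table needs 'time' and 'event' columns")
  if (any(table$time < 0))
    stop("survival times must be nonnegative")
  if (!all(table$event %in% c(0, 1)))
    stop("event flags must be 0 or 1")
  if (!"group" %in% names(table))
    table$group <- "all"
  if (sum(table$event) == 0)
    stop("degenerate survival data: no events observed")
  table
}
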