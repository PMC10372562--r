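#' Local event table for federated survival analysis
#'
#' The Kaplan-Meier estimator and the log-rank test depend on the records
#' only through per-time-point counts: events at each distinct event time,
#' censorings at each distinct censoring time, and the total at risk.
#' These counts are summable across parties, so pooling event tables is
#' exact federation.  Ties between deaths and censorings at the same time
#' follow the standard convention: subjects censored at `t` are still at
#' risk for events at `t`.
#'
#' Exact per-time counts are disclosed to the coordinator; for very small
#' cells this is a known disclosure risk, and the counts can be summed
#' through [secure_sum()] when parties share a common time grid.
#'
#' @param data Data frame with a nonnegative `time` column and a 0/1
#'   `event` column (1 = event, 0 = censored).
#' @param time,event Column names.
#' @return Object of class `event_table`: `n_total`, tibble `events`
#'   (`time`, `d`), tibble `censored` (`time`, `c`).
#' @export
local_event_table <- function(data, time = "time", event = "event") {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  tt <- data[[time]]
  ev <- data[[event]]
  if (any(tt < 0)) stop("validation error: negative survival time", call. = FALSE)
  stopifnot(all(ev %in% c(0, 1)))
  count_times <- function(v) {
    u <- sort(unique(v))  # numeric sort, no character round-trip
    tibble::tibble(time = u,
                   n = vapply(u, function(t) sum(v == t), integer(1)))
  }
  ev_tab <- count_times(tt[ev == 1])
  cn_tab <- count_times(tt[ev == 0])
  structure(
    list(
      n_total = length(tt),
      events = tibble::tibble(time = ev_tab$time, d = ev_tab$n),
      censored = tibble::tibble(time = cn_tab$time, c = cn_tab$n)
    ),
    class = "event_table"
  )
}

#' Pool event tables across parties
#'
#' Unions the time points, sums event and censoring counts, and sums the
#' totals; the result is exactly the event table of the pooled records.
#'
#' @param tables List of [local_event_table()] objects.
#' @return A pooled `event_table`.
#' @export
aggregate_tables <- function(tables) {
  stopifnot(length(tables) >= 1)
  sum_counts <- function(dfs, count_col) {
    all <- dplyr::bind_rows(dfs)
    if (nrow(all) == 0) {
      return(tibble::tibble(time = numeric(0), !!count_col := integer(0)))
    }
    all |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(!!count_col := as.integer(sum(.data[[count_col]])),
                       .groups = "drop") |>
      dplyr::arrange(.data$time)
  }
  structure(
    list(
      n_total = sum(vapply(tables, function(t) t$n_total, numeric(1))),
      events = sum_counts(lapply(tables, function(t) t$events), "d"),
      censored = sum_counts(lapply(tables, function(t) t$censored), "c")
    ),
    class = "event_table"
  )
}

# number at risk just before each requested time: total minus all events
# and censorings strictly before t (censoring at t is still at risk at t)
at_risk_at <- function(table, times) {
  vapply(times, function(t) {
    table$n_total -
      sum(table$events$d[table$events$time < t]) -
      sum(table$censored$c[table$censored$time < t])
  }, numeric(1))
}

#' Tidy per-time view of an event table
#'
#' @param x An `event_table`.
#' @param ... Unused.
#' @return Tibble with `time`, `n_risk`, `n_event`, `n_censor_interval`
#'   (censorings in `[t_i, t_{i+1})`).
#' @method tidy event_table
#' @export
tidy.event_table <- function(x, ...) {
  times <- x$events$time
  nxt <- c(times[-1], Inf)
  cens <- vapply(seq_along(times), function(i) {
    sum(x$censored$c[x$censored$time >= times[i] & x$censored$time < nxt[i]])
  }, numeric(1))
  tibble::tibble(
    time = times,
    n_risk = at_risk_at(x, times),
    n_event = x$events$d,
    n_censor_interval = as.integer(cens)
  )
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("Event table: n = %d, %d distinct event times, %d censored\n",
              x$n_total, nrow(x$events), sum(x$censored$c)))
  if (nrow(x$events) > 0) print(tidy.event_table(x))
  invisible(x)
}

#' Kaplan-Meier survival curve from an event table
#'
#' Product-limit estimator `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over
#' the distinct event times, with `S(0) = 1` and a right-continuous step
#' between event times.
#'
#' @param table An [local_event_table()] or [aggregate_tables()] result.
#' @return Object of class `km_curve`: a tibble with `time`, `n_risk`,
#'   `n_event`, `survival` (rows only at event times; `S = 1` before the
#'   first).
#' @export
km_curve <- function(table) {
  stopifnot(inherits(table, "event_table"))
  times <- table$events$time
  if (length(times) == 0) {
    out <- tibble::tibble(time = numeric(0), n_risk = numeric(0),
                          n_event = integer(0), survival = numeric(0))
  } else {
    n_risk <- at_risk_at(table, times)
    out <- tibble::tibble(
      time = times,
      n_risk = n_risk,
      n_event = table$events$d,
      survival = cumprod(1 - table$events$d / n_risk)
    )
  }
  class(out) <- c("km_curve", class(out))
  attr(out, "n_total") <- table$n_total
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param curve A [km_curve()].
#' @param times Numeric vector of evaluation times.
#' @return `S(times)` as a numeric vector.
#' @export
km_survival_at <- function(curve, times) {
  vapply(times, function(t) {
    past <- curve$survival[curve$time <= t]
    if (length(past) == 0) 1 else past[length(past)]
  }, numeric(1))
}

#' Log-rank test from per-group event tables
#'
#' The standard (Mantel-Haenszel) log-rank test: at each pooled event time
#' the expected events in group `g` are `n_g d / n` and the variance terms
#' come from the hypergeometric distribution of the 2 x k table.  The
#' statistic is invariant to how records are split across parties because
#' it only sees the aggregated per-group tables.
#'
#' @param group_tables Named list mapping group label to an `event_table`
#'   (each typically an [aggregate_tables()] over that group's parties).
#' @return Object of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   tibble `observed_expected` per group.
#' @export
logrank_test <- function(group_tables) {
  k <- length(group_tables)
  if (k < 2) stop("log-rank test needs at least 2 groups", call. = FALSE)
  groups <- names(group_tables)
  if (is.null(groups)) groups <- paste0("group", seq_len(k))
  all_times <- sort(unique(unlist(lapply(group_tables,
                                         function(t) t$events$time))))
  if (length(all_times) == 0) {
    stop("log-rank statistic undefined: no events observed", call. = FALSE)
  }
  obs <- rep(0, k)
  expd <- rep(0, k)
  v <- matrix(0, k, k)
  for (t in all_times) {
    n_g <- vapply(group_tables, at_risk_at, numeric(1), times = t)
    d_g <- vapply(group_tables, function(tb) {
      i <- match(t, tb$events$time)
      if (is.na(i)) 0 else tb$events$d[i]
    }, numeric(1))
    n <- sum(n_g)
    d <- sum(d_g)
    if (d == 0) next
    obs <- obs + d_g
    expd <- expd + n_g * d / n
    # hypergeometric covariance: V_gh = d (n - d) (n delta_gh n_g - n_g n_h) / (n^2 (n - 1))
    if (n > 1) {
      scale <- d * (n - d) / ((n - 1) * n^2)
      v <- v + scale * (diag(n_g * n, k) - outer(n_g, n_g))
    }
  }
  z <- (obs - expd)[-k]
  vz <- v[-k, -k, drop = FALSE]
  stat <- drop(t(z) %*% solve(vz, z))
  df <- k - 1
  structure(
    list(
      statistic = stat,
      df = df,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE),
      observed_expected = tibble::tibble(
        group = groups, observed = obs, expected = expd
      )
    ),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$observed_expected)
  invisible(x)
}

#' Federated Kaplan-Meier analysis over party data frames
#'
#' Builds each party's event table(s) locally, pools them at the
#' coordinator, and returns survival curve(s) plus a log-rank test when a
#' grouping column is present.  Results are identical to a centralized
#' analysis of the pooled records.
#'
#' @param data_list List of data frames with `time` and `event` columns
#'   and optionally `group`.
#' @param time,event,group Column names (`group = NULL` for one curve).
#' @return Object of class `fed_km_fit`: `curves` (named list of
#'   [km_curve()]), `tables`, and `logrank` (or `NULL`).
#' @export
fed_kaplan_meier <- function(data_list, time = "time", event = "event",
                             group = NULL) {
  has_group <- !is.null(group) && group %in% names(data_list[[1]])
  if (!has_group) {
    tabs <- lapply(data_list, local_event_table, time = time, event = event)
    pooled <- aggregate_tables(tabs)
    out <- list(curves = list(overall = km_curve(pooled)),
                tables = list(overall = pooled), logrank = NULL)
  } else {
    levels <- sort(unique(unlist(lapply(data_list, function(d) d[[group]]))))
    tables <- lapply(levels, function(g) {
      local <- lapply(data_list, function(d) {
        sub <- d[d[[group]] == g, , drop = FALSE]
        if (nrow(sub) == 0) NULL else local_event_table(sub, time, event)
      })
      aggregate_tables(Filter(Negate(is.null), local))
    })
    names(tables) <- as.character(levels)
    out <- list(
      curves = lapply(tables, km_curve),
      tables = tables,
      logrank = if (length(tables) >= 2) logrank_test(tables) else NULL
    )
  }
  structure(out, class = "fed_km_fit")
}

#' @export
print.fed_km_fit <- function(x, ...) {
  cat(sprintf("Federated Kaplan-Meier fit: %d curve(s)\n", length(x$curves)))
  for (g in names(x$curves)) {
    cv <- x$curves[[g]]
    cat(sprintf("  %s: n = %d, %d event times, final S = %.4f\n",
                g, attr(cv, "n_total"), nrow(cv),
                if (nrow(cv)) cv$survival[nrow(cv)] else 1))
  }
  if (!is.null(x$logrank)) print(x$logrank)
  invisible(x)
}
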