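#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a federated linear fit
#'
#' @param x A `fed_linear_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy fed_linear_fit
#' @export
tidy.fed_linear_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% paste0("x", seq_along(x$beta)),
                 estimate = unname(x$beta))
}

#' @rdname tidy.fed_linear_fit
#' @method glance fed_linear_fit
#' @export
glance.fed_linear_fit <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, n_parties = x$n_parties,
                 singular = x$singular)
}

#' Tidy a federated logistic fit
#'
#' @param x A `fed_logistic_fit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @method tidy fed_logistic_fit
#' @export
tidy.fed_logistic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta) %||% paste0("x", seq_along(x$beta)),
                 estimate = unname(x$beta))
}

#' @rdname tidy.fed_logistic_fit
#' @method glance fed_logistic_fit
#' @export
glance.fed_logistic_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_parties = x$n_parties,
                 iterations = x$iterations, converged = x$converged,
                 deviance = x$deviance)
}

#' Tidy a merged federated forest
#'
#' @param x A `fed_forest`.
#' @param ... Unused.
#' @return Tibble with one row per contributing party: `party`, `n_trees`.
#' @method tidy fed_forest
#' @export
tidy.fed_forest <- function(x, ...) {
  tibble::tibble(
    party = vapply(x$members, function(m) m$party, numeric(1)),
    n_trees = vapply(x$members, function(m) m$n_trees, numeric(1)),
    constant = vapply(x$members, function(m) m$constant, logical(1))
  ) |>
    dplyr::group_by(.data$party) |>
    dplyr::summarise(n_trees = sum(.data$n_trees),
                     constant = any(.data$constant), .groups = "drop")
}

#' @rdname tidy.fed_forest
#' @method glance fed_forest
#' @export
glance.fed_forest <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, task = x$task,
                 n_parties = length(unique(
                   vapply(x$members, function(m) m$party, numeric(1)))))
}

#' Tidy a Kaplan-Meier curve
#'
#' @param x A `km_curve`.
#' @param ... Unused.
#' @return The underlying tibble (`time`, `n_risk`, `n_event`,
#'   `survival`).
#' @method tidy km_curve
#' @export
tidy.km_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "n_risk", "n_event", "survival")])
}

#' Tidy a cross-validation report
#'
#' @param x A `fed_cv_report`.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy fed_cv_report
#' @export
tidy.fed_cv_report <- function(x, ...) x$per_fold

#' @rdname tidy.fed_cv_report
#' @method glance fed_cv_report
#' @export
glance.fed_cv_report <- function(x, ...) x$summary

#' Step plot of survival curves
#'
#' @param object A `km_curve` or `fed_km_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tidy.km_curve(object)[c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "S(t)",
                  title = "Kaplan-Meier survival curve") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_curve
#' @method autoplot fed_km_fit
#' @export
autoplot.fed_km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(names(object$curves), function(g) {
    cv <- object$curves[[g]]
    dplyr::bind_rows(
      tibble::tibble(time = 0, survival = 1),
      tidy.km_curve(cv)[c("time", "survival")]
    ) |>
      dplyr::mutate(group = g)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "S(t)",
                  title = "Federated Kaplan-Meier curves") +
    ggplot2::theme_minimal()
}

#' Box plot of per-fold metrics
#'
#' The comparison plot for centralized vs federated vs local-only runs:
#' pass several reports to overlay their fold distributions.
#'
#' @param object A `fed_cv_report`.
#' @param ... Optionally further named `fed_cv_report`s to compare.
#' @return A ggplot object.
#' @method autoplot fed_cv_report
#' @export
autoplot.fed_cv_report <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "fed_cv_report")]
  reports <- c(list(object), extra)
  nms <- names(reports)
  if (is.null(nms)) nms <- rep("", length(reports))
  nms[nms == ""] <- paste0("report", seq_along(reports))[nms == ""]
  df <- dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(reports[[i]]$per_fold, setting = nms[i])
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$setting, y = .data$metric)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(y = object$metric_name, x = NULL,
                  title = "Per-fold metric distribution") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a federated MLP
#'
#' @param object A `fed_mlp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fed_mlp_fit
#' @export
autoplot.fed_mlp_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$round, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "FedAvg training loss", x = "round",
                  y = "weighted training loss") +
    ggplot2::theme_minimal()
}

#' Network-traffic plot for a workflow run
#'
#' @param log A message-log tibble, `fed_session`, or
#'   `fed_workflow_result`.
#' @return A ggplot object: bytes per round, colored by payload kind.
#' @export
plot_traffic <- function(log) {
  ts <- traffic_summary(log)
  ggplot2::ggplot(ts, ggplot2::aes(x = .data$round, y = .data$bytes,
                                   fill = .data$payload_kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(title = "Simulated network traffic", x = "round",
                  y = "bytes") +
    ggplot2::theme_minimal()
}
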