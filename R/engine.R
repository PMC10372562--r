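#' Payload kinds allowed on the wire
#'
#' Every message in a workflow carries one of these kinds; raw feature
#' matrices and label vectors are never among them.  The privacy audit
#' ([audit_message_log()]) checks the full log against this whitelist.
#'
#' @export
PAYLOAD_KINDS <- c(
  "ack", "fold_counts", "moment_stats", "standardize_params",
  "gram_stats", "beta", "gradient_hessian", "sample_count",
  "tree_allocation", "tree_list", "global_model", "model_params",
  "confusion_counts", "error_sums", "report", "event_table",
  "survival_result", "category_set", "category_list",
  "secret_share", "partial_sum", "secure_aggregate", "done"
)

#' Open an in-memory federated session
#'
#' Simulates the star topology on one machine: party id 0 is the
#' coordinator, ids `1..n_parties` are data-holding participants.  All
#' traffic goes through [party_send()], [gather()], and [broadcast()],
#' which append to a message log with byte-size accounting (8 bytes per
#' float64 element, JSON length for structured payloads), so the
#' communication pattern and volume of a real deployment can be audited
#' even though execution is in-process.
#'
#' By default the coordinator also holds data (dual role): party 1 runs on
#' the coordinator's machine, which changes nothing about the simulated
#' message pattern.
#'
#' @param n_parties Number of data-holding participants (>= 1).
#' @param coordinator_has_data Does the coordinator double as party 1?
#' @param seed Session seed recorded for derived randomness.
#' @return An environment of class `fed_session`.
#' @export
fed_session <- function(n_parties, coordinator_has_data = TRUE, seed = NULL) {
  stopifnot(n_parties >= 1)
  s <- new.env(parent = emptyenv())
  s$n_parties <- as.integer(n_parties)
  s$coordinator_has_data <- isTRUE(coordinator_has_data)
  s$seed <- seed
  s$log <- list()
  s$outbox <- list()   # per-round party submissions awaiting gather()
  s$inbox <- list()    # last broadcast payload
  s$round <- 0L
  class(s) <- "fed_session"
  s
}

#' @export
print.fed_session <- function(x, ...) {
  cat(sprintf("<fed_session> %d participant(s) + coordinator%s, %d message(s) logged\n",
              x$n_parties,
              if (x$coordinator_has_data) " (holds data)" else "",
              length(x$log)))
  invisible(x)
}

# serialized size in bytes: raw little-endian float64 for numeric blocks,
# canonical JSON for structured payloads, native serialization for opaque
# model objects (fitted forests)
payload_bytes <- function(payload) {
  if (is.null(payload)) return(0)
  if (is.numeric(payload) || is.logical(payload)) return(8 * length(payload))
  if (is.character(payload)) return(sum(nchar(payload, type = "bytes")))
  if (inherits(payload, "randomForest") || inherits(payload, "fed_forest")) {
    return(length(serialize(payload, NULL)))
  }
  if (is.list(payload)) {
    plain <- all(vapply(payload, function(p) {
      is.numeric(p) || is.logical(p) || is.character(p) || is.null(p) || is.list(p)
    }, logical(1)))
    if (plain) return(sum(vapply(payload, payload_bytes, numeric(1))))
  }
  length(serialize(payload, NULL))
}

log_message <- function(session, sender, recipient, round, payload_kind,
                        payload) {
  session$log[[length(session$log) + 1]] <- list(
    sender = as.integer(sender), recipient = as.integer(recipient),
    round = as.integer(round), payload_kind = payload_kind,
    byte_size = payload_bytes(payload)
  )
  invisible(session)
}

#' Submit a participant's payload for a round
#'
#' Participants may only address the coordinator (recipient 0); the single
#' exception is `payload_kind = "secret_share"`, which the engine relays
#' between parties without the coordinator being able to decode it.
#'
#' @param session A [fed_session()].
#' @param party_id Sending participant (1-based).
#' @param payload The payload object.
#' @param kind A payload kind from [PAYLOAD_KINDS].
#' @param round Round number; defaults to the session's current round.
#' @param recipient Recipient id (0 = coordinator).
#' @return The session, invisibly.
#' @export
party_send <- function(session, party_id, payload, kind, round = session$round,
                       recipient = 0L) {
  stopifnot(party_id >= 1, party_id <= session$n_parties)
  if (!kind %in% PAYLOAD_KINDS) {
    stop(sprintf("unknown payload kind '%s'", kind), call. = FALSE)
  }
  if (recipient != 0L && kind != "secret_share") {
    stop("participant-to-participant messages are forbidden except secret shares",
         call. = FALSE)
  }
  log_message(session, party_id, recipient, round, kind, payload)
  if (recipient == 0L) {
    key <- paste0("r", round)
    if (is.null(session$outbox[[key]])) {
      session$outbox[[key]] <- vector("list", session$n_parties)
    }
    session$outbox[[key]][[party_id]] <- list(payload = payload, kind = kind)
  }
  invisible(session)
}

#' Collect all participant payloads for a round at the coordinator
#'
#' Barrier-synchronized: aggregation only proceeds once every participant
#' has submitted (so a run's progress is gated by the slowest party, as in
#' a real deployment).  A missing submission raises a timeout error naming
#' the missing party.
#'
#' @param session A [fed_session()].
#' @param round Round number.
#' @param payload_kind Expected kind; a mismatch is a protocol error.
#' @return List of payloads ordered by party id.
#' @export
gather <- function(session, round, payload_kind) {
  key <- paste0("r", round)
  box <- session$outbox[[key]]
  present <- !vapply(seq_len(session$n_parties), function(p) {
    is.null(box) || is.null(box[[p]])
  }, logical(1))
  if (!all(present)) {
    stop(sprintf("timeout waiting for party %s in round %d",
                 paste(which(!present), collapse = ", "), round),
         call. = FALSE)
  }
  kinds <- vapply(box, function(b) b$kind, character(1))
  if (!all(kinds == payload_kind)) {
    stop(sprintf("protocol error: expected payload kind '%s', got '%s'",
                 payload_kind, paste(unique(kinds), collapse = ",")),
         call. = FALSE)
  }
  session$outbox[[key]] <- NULL
  lapply(box, function(b) b$payload)
}

#' Broadcast a payload from the coordinator to every participant
#'
#' Only the coordinator may broadcast; one message per recipient is
#' logged, so the broadcast cost scales with the number of participants.
#'
#' @param session A [fed_session()].
#' @param round Round number.
#' @param payload The payload object.
#' @param kind A payload kind from [PAYLOAD_KINDS].
#' @param from Sender id; anything but 0 is a role violation.
#' @return The session, invisibly.
#' @export
broadcast <- function(session, round, payload, kind, from = 0L) {
  if (from != 0L) {
    stop("role violation: only the coordinator may broadcast", call. = FALSE)
  }
  if (!kind %in% PAYLOAD_KINDS) {
    stop(sprintf("unknown payload kind '%s'", kind), call. = FALSE)
  }
  for (p in seq_len(session$n_parties)) {
    log_message(session, 0L, p, round, kind, payload)
  }
  session$inbox <- list(payload = payload, kind = kind, round = round)
  invisible(session)
}

#' The session message log as a tibble
#'
#' @param session A [fed_session()] (or a workflow result).
#' @return Tibble with `sender`, `recipient`, `round`, `payload_kind`,
#'   `byte_size`.
#' @export
message_log <- function(session) {
  log <- if (inherits(session, "fed_workflow_result")) session$message_log
  else session$log
  if (is.tbl_log(log)) return(log)
  dplyr::bind_rows(lapply(log, tibble::as_tibble))
}

is.tbl_log <- function(x) inherits(x, "data.frame")

#' Audit a message log against the payload-kind whitelist
#'
#' The engine's privacy pattern: raw features and labels never travel, so
#' every logged payload kind must be on the whitelist.  Returns `TRUE`
#' invisibly or raises an error listing the offending kinds.
#'
#' @param log A tibble from [message_log()] or a `fed_session`.
#' @param whitelist Allowed kinds.
#' @return `TRUE` (invisibly) if the audit passes.
#' @export
audit_message_log <- function(log, whitelist = PAYLOAD_KINDS) {
  if (inherits(log, "fed_session") || inherits(log, "fed_workflow_result")) {
    log <- message_log(log)
  }
  bad <- setdiff(unique(log$payload_kind), whitelist)
  if (length(bad) > 0) {
    stop(sprintf("privacy audit failed: payload kind(s) %s not whitelisted",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Per-round traffic summary of a message log
#'
#' @param log A message-log tibble, `fed_session`, or workflow result.
#' @return Tibble with one row per round x direction x payload kind:
#'   message counts and total bytes.
#' @export
traffic_summary <- function(log) {
  if (!is.tbl_log(log)) log <- message_log(log)
  log |>
    dplyr::mutate(direction = ifelse(.data$sender == 0, "broadcast",
                                     ifelse(.data$recipient == 0,
                                            "to_coordinator", "party_to_party"))) |>
    dplyr::group_by(.data$round, .data$direction, .data$payload_kind) |>
    dplyr::summarise(messages = dplyr::n(), bytes = sum(.data$byte_size),
                     .groups = "drop")
}

# ---- app registry -----------------------------------------------------------

.app_registry <- new.env(parent = emptyenv())

#' Register a federated app
#'
#' An app is the unit a workflow chains: a participant phase run at every
#' party (returning an outbound payload) and a coordinator phase over the
#' gathered payloads (returning a broadcast and/or the final result),
#' iterated until the app signals completion.
#'
#' @param name App name used in workflow configs.
#' @param app List with elements `consumes`, `produces`,
#'   `participant_phase(state, broadcast_in, params, ctx)` returning
#'   `list(state, payload, kind)`,
#'   `coordinator_phase(cstate, payloads, params, ctx)` returning
#'   `list(state, broadcast, kind, done, final, report)`, and optionally
#'   `finalize(state, final, params, ctx)` and `secure_cap` (TRUE if the
#'   app's payload is a flat summable vector eligible for secret sharing).
#' @return `name`, invisibly.
#' @export
register_app <- function(name, app) {
  stopifnot(is.character(name), is.list(app),
            is.function(app$participant_phase),
            is.function(app$coordinator_phase))
  app$name <- name
  assign(name, app, envir = .app_registry)
  invisible(name)
}

#' @rdname register_app
#' @export
list_apps <- function() sort(ls(.app_registry))

get_app <- function(name) {
  if (!exists(name, envir = .app_registry)) {
    stop(sprintf("configuration error: unknown app '%s'", name),
         call. = FALSE)
  }
  get(name, envir = .app_registry)
}

# ---- workflow configuration -------------------------------------------------

#' Build a workflow configuration
#'
#' @param workflow List of [wf_step()]s, executed in order.
#' @param n_parties Number of participants.
#' @param seed Master seed; all derived randomness flows from it.
#' @param secure_aggregation Route summable aggregations through additive
#'   secret sharing (requires >= 3 parties)?
#' @param coordinator_has_data Coordinator dual role flag.
#' @param label Label column name in the party data.
#' @return A list of class `workflow_config`.
#' @export
workflow_config <- function(workflow, n_parties, seed = 1L,
                            secure_aggregation = FALSE,
                            coordinator_has_data = TRUE, label = "y") {
  structure(
    list(workflow = workflow, n_parties = as.integer(n_parties),
         seed = as.integer(seed),
         secure_aggregation = isTRUE(secure_aggregation),
         coordinator_has_data = isTRUE(coordinator_has_data),
         label = label),
    class = "workflow_config"
  )
}

#' @rdname workflow_config
#' @param app App name.
#' @param ... App parameters (e.g. `k = 10` for the cv app).
#' @param consumes,produces Optional slot overrides; defaults come from
#'   the app registry, and the produced slot of each step must equal the
#'   consumed slot of the next.
#' @export
wf_step <- function(app, ..., consumes = NULL, produces = NULL) {
  list(app = app, params = list(...), consumes = consumes,
       produces = produces)
}

validate_workflow <- function(config) {
  steps <- config$workflow
  if (length(steps) == 0) {
    stop("configuration error: empty workflow", call. = FALSE)
  }
  slots <- lapply(steps, function(st) {
    app <- get_app(st$app)
    list(consumes = st$consumes %||% app$consumes,
         produces = st$produces %||% app$produces)
  })
  for (i in seq_along(slots)[-1]) {
    if (!identical(slots[[i - 1]]$produces, slots[[i]]$consumes)) {
      stop(sprintf(
        "configuration error: step %d ('%s') produces slot '%s' but step %d ('%s') consumes '%s'",
        i - 1, steps[[i - 1]]$app, slots[[i - 1]]$produces,
        i, steps[[i]]$app, slots[[i]]$consumes), call. = FALSE)
    }
  }
  slots
}

# ---- secure aggregation inside the engine ----------------------------------

# Full share choreography with message logging: every party splits its
# secret, shares travel party-to-party (kind secret_share, relayed blind
# through the coordinator), each party sends its partial sum to the
# coordinator, which reconstructs the total.
engine_secure_sum <- function(session, round, secrets, codec, seed) {
  n <- length(secrets)
  bundles <- lapply(seq_len(n), function(i) {
    make_shares(secrets[[i]], n, codec,
                rng_seed = if (is.null(seed)) NULL else make_seed(seed, round, i))
  })
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        log_message(session, i, j, round, "secret_share",
                    bundles[[i]]$shares[j, ])
      }
    }
  }
  partials <- lapply(seq_len(n), function(j) {
    pj <- combine_received(lapply(bundles, function(b) b$shares[j, ]), codec)
    log_message(session, j, 0L, round, "partial_sum", pj)
    pj
  })
  reconstruct_sum(partials, codec)
}

# ---- workflow execution -----------------------------------------------------

#' Run a federated workflow over party datasets
#'
#' Executes each step's participant phase at every party, then the
#' coordinator's aggregation phase, iterating multi-round apps until they
#' signal completion.  Intermediate per-party outputs stay in each party's
#' local state (retrievable from the result, absent from any cross-party
#' message); the final result of the last step is broadcast to all
#' parties.  An app failure aborts the workflow with the failing step
#' identified, so the run can be fixed and rerun.
#'
#' @param config A [workflow_config()].
#' @param datasets List of party data frames (length `n_parties`).
#' @return Object of class `fed_workflow_result`: `final_outputs` (one per
#'   party), `per_step_reports` (one per step, in order), `message_log`
#'   tibble, `party_states`, `config`.
#' @examples
#' d <- synth_dataset("regression", 150, 3, seed = 5)
#' parts <- partition_parties(d, c(0.5, 0.5), seed = 5)
#' cfg <- workflow_config(
#'   list(wf_step("cv", k = 3), wf_step("normalization"),
#'        wf_step("linear_regression"), wf_step("eval_regression")),
#'   n_parties = 2, seed = 5)
#' res <- run_workflow(cfg, parts)
#' res$per_step_reports$eval_regression$summary
#' @export
run_workflow <- function(config, datasets) {
  stopifnot(inherits(config, "workflow_config"))
  if (length(datasets) != config$n_parties) {
    stop("configuration error: need one dataset per party", call. = FALSE)
  }
  slots <- validate_workflow(config)
  if (config$secure_aggregation && config$n_parties < 3) {
    stop("protocol error: secure aggregation requires at least 3 parties",
         call. = FALSE)
  }
  set.seed(config$seed)
  session <- fed_session(config$n_parties, config$coordinator_has_data,
                         seed = config$seed)
  states <- lapply(seq_len(config$n_parties), function(p) {
    e <- new.env(parent = emptyenv())
    e$data <- datasets[[p]]
    e$party_id <- p
    e
  })
  reports <- list()
  codec <- fp_codec()
  for (i in seq_along(config$workflow)) {
    st <- config$workflow[[i]]
    app <- get_app(st$app)
    params <- st$params
    params$label <- params$label %||% config$label
    step_result <- tryCatch(
      run_app(session, app, states, params, config, codec, step_index = i),
      error = function(e) {
        stop(structure(
          class = c("fedsilo_workflow_error", "error", "condition"),
          list(message = sprintf(
            "workflow aborted at step %d ('%s'): %s", i, st$app,
            conditionMessage(e)),
            call = NULL, step = i, app = st$app)
        ))
      }
    )
    reports[[st$app]] <- step_result$report
    last_slot <- slots[[i]]$produces
  }
  structure(
    list(
      final_outputs = lapply(states, function(s) get0(last_slot, envir = s)),
      per_step_reports = reports,
      message_log = message_log(session),
      party_states = states,
      config = config
    ),
    class = "fed_workflow_result"
  )
}

run_app <- function(session, app, states, params, config, codec, step_index) {
  n <- config$n_parties
  secure <- config$secure_aggregation && isTRUE(app$secure_cap)
  cstate <- list()
  broadcast_in <- NULL
  report <- NULL
  repeat {
    session$round <- session$round + 1L
    round <- session$round
    results <- vector("list", n)
    for (p in seq_len(n)) {
      ctx <- list(party_id = p, n_parties = n, round = round,
                  seed = make_seed(config$seed, step_index, p),
                  secure = secure)
      results[[p]] <- app$participant_phase(states[[p]], broadcast_in,
                                            params, ctx)
      if (!is.null(results[[p]]$state)) {
        # participant phases mutate the state environment in place;
        # the returned state element is accepted for value-style apps
        if (is.environment(results[[p]]$state)) states[[p]] <- results[[p]]$state
      }
    }
    kind <- results[[1]]$kind %||% "ack"
    if (secure && identical(kind, "secure_aggregate")) {
      secrets <- lapply(results, function(r) r$payload)
      total <- engine_secure_sum(session, round, secrets, codec,
                                 seed = make_seed(config$seed, step_index))
      payloads <- structure(list(sum = total), secure = TRUE)
    } else {
      for (p in seq_len(n)) {
        party_send(session, p, results[[p]]$payload, kind, round)
      }
      payloads <- gather(session, round, kind)
    }
    ctx0 <- list(n_parties = n, round = round,
                 seed = make_seed(config$seed, step_index),
                 secure = secure)
    co <- app$coordinator_phase(cstate, payloads, params, ctx0)
    cstate <- co$state %||% cstate
    if (isTRUE(co$done)) {
      final <- co$final %||% co$report %||% "done"
      final_kind <- co$kind %||% "report"
      broadcast(session, round, final, final_kind)
      if (is.function(app$finalize)) {
        for (p in seq_len(n)) {
          ctx <- list(party_id = p, n_parties = n, round = round,
                      seed = make_seed(config$seed, step_index, p),
                      secure = secure)
          app$finalize(states[[p]], final, params, ctx)
        }
      }
      report <- co$report
      break
    }
    broadcast(session, round, co$broadcast, co$kind %||% "report")
    broadcast_in <- co$broadcast
  }
  list(report = report)
}

#' @export
print.fed_workflow_result <- function(x, ...) {
  cat(sprintf("Federated workflow result: %d step(s), %d part(ies), %d message(s)\n",
              length(x$per_step_reports), x$config$n_parties,
              nrow(x$message_log)))
  cat("Steps:", paste(names(x$per_step_reports), collapse = " -> "), "\n")
  invisible(x)
}

# helper used by apps and payloads alike
is_secure_payloads <- function(payloads) isTRUE(attr(payloads, "secure"))
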