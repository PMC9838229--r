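# The virtual neurological substrate: thread templates grouped into disjoint
# streams, integer weights (with an absorbing BLOCKED state) on
# sender->receiver pairs, weight-gated asynchronous signals, and the
# join/merge coincidence primitive on which long-term potentiation rests.
#
# A model is a mutable environment (class "vcog_model"); all substrate and
# plasticity operations mutate it in place and log trace events.

BLOCKED <- "BLOCKED"

default_config <- function() {
  list(
    threshold = 1L,          # theta: minimum weight for a gated pathway to transmit
    signal_ttl = 1L,         # undelivered signals survive this many extra cycles
    coincidence_window = 1L, # |t_join - t_merge| tolerance, in cycles
    stp_duration = 1L,       # default short-term potentiation, in cycles
    pass_limit = 8L,         # react passes per cycle before truncation
    mode = "strong"          # plasticity mode: "weak" or "strong"
  )
}

#' Create an empty model
#'
#' A model bundles the full mutable state of the virtual machine: thread
#' templates and active instances, the weight table, the signal queue,
#' join/merge registries, the associative store, short-term FIFO memories,
#' the cycle counter and the ordered trace.
#'
#' @param config named list overriding entries of the default run
#'   configuration (`threshold`, `signal_ttl`, `coincidence_window`,
#'   `stp_duration`, `pass_limit`, `mode`).
#' @return an environment of class `vcog_model`.
#' @export
new_model <- function(config = list()) {
  m <- new.env(parent = emptyenv())
  cfg <- default_config()
  cfg[names(config)] <- config
  cfg$mode <- match.arg(cfg$mode, c("strong", "weak"))
  m$config <- cfg
  m$templates <- list()
  m$rulebase <- list()
  m$weights <- new.env(parent = emptyenv())
  m$stp <- list()
  m$queue <- list()
  m$joins <- list()
  m$merges <- list()
  m$protocols <- list()
  m$instances <- list()
  m$store <- list()        # associative store {P}: newest first
  m$stm <- new.env(parent = emptyenv())  # per-tag FIFO <t>
  m$trace <- list()
  m$actions <- list()
  m$applied <- new.env(parent = emptyenv())
  m$choice_done <- new.env(parent = emptyenv())
  m$pending <- list()      # world feedback stimuli keyed by cycle
  m$dropped <- list()
  m$cycle <- 1L
  m$next_id <- 0L
  m$truncated <- FALSE
  class(m) <- c("vcog_model", class(m))
  m
}

new_id <- function(m) {
  m$next_id <- m$next_id + 1L
  m$next_id
}

trace_event <- function(m, kind, text) {
  m$trace[[length(m$trace) + 1L]] <- list(cycle = m$cycle, kind = kind, text = text)
  invisible(m)
}

#' Register a thread template
#'
#' @param m a model.
#' @param name template name, unique within the circuit.
#' @param kind one of `sensor`, `effector`, `internal`, `plasticity`.
#' @param stream stream identifier; streams partition threads and gate all
#'   weighted communication.
#' @param pattern the template's term pattern (a `vcog_term`).
#' @param ttl number of cycles an activated instance stays active.
#' @return the model, invisibly.
#' @export
add_template <- function(m, name, kind, stream, pattern, ttl = 1L) {
  if (!is.null(m$templates[[name]])) stop(sprintf("duplicate template '%s'", name))
  m$templates[[name]] <- list(name = name, kind = kind, stream = stream,
                              pattern = pattern, ttl = as.integer(ttl))
  invisible(m)
}

## ---- weight table ----------------------------------------------------------

wkey <- function(stream, from, to) paste(stream, from, to, sep = "\r")

#' Initialize or inspect a weighted pathway
#'
#' Weights are integers >= 0 or `BLOCKED`; `BLOCKED` is absorbing (no
#' operation restores a blocked entry). "Open at start" pathways initialize
#' at weight 1, "closed" at 0.
#'
#' @param m model; `stream`, `from`, `to` identify the pathway.
#' @param w initial integer weight.
#' @return `weight_init`: the model, invisibly. `get_weight`: the integer
#'   weight or the string `"BLOCKED"`.
#' @export
weight_init <- function(m, stream, from, to, w = 1L) {
  m$weights[[wkey(stream, from, to)]] <-
    list(stream = stream, from = from, to = to, w = as.integer(w),
         blocked = FALSE, gkey = NULL)
  invisible(m)
}

#' @rdname weight_init
#' @export
get_weight <- function(m, stream, from, to) {
  e <- m$weights[[wkey(stream, from, to)]]
  if (is.null(e)) return(0L)
  if (e$blocked) return(BLOCKED)
  e$w
}

stp_floor <- function(m, key) {
  for (s in m$stp) {
    if (s$key == key && m$cycle <= s$until) return(m$config$threshold)
  }
  0L
}

# Effective gate for a signal on (stream, from, to): list(open=, payload=)
# where payload is rewritten to the frozen ground instance on a
# weakly-potentiated pathway.
gate_check <- function(m, stream, from, to, payload) {
  key <- wkey(stream, from, to)
  e <- m$weights[[key]]
  if (is.null(e)) return(list(open = FALSE, blocked = FALSE, payload = payload))
  if (e$blocked) return(list(open = FALSE, blocked = TRUE, payload = payload))
  w <- max(e$w, stp_floor(m, key))
  if (w < m$config$threshold) return(list(open = FALSE, blocked = FALSE, payload = payload))
  if (!is.null(e$gkey)) payload <- e$gkey   # weak pathway replays its bound instance
  list(open = TRUE, blocked = FALSE, payload = payload)
}

#' Adjust a pathway weight
#'
#' Applies `delta` with a floor at 0. Adjusting a `BLOCKED` edge is a
#' logged no-op, never an error: blocking is absorbing.
#'
#' @inheritParams weight_init
#' @param delta integer increment (LTP uses +1, LTD -1).
#' @return the model, invisibly.
#' @export
adjust_weight <- function(m, stream, from, to, delta) {
  key <- wkey(stream, from, to)
  e <- m$weights[[key]]
  if (is.null(e)) {
    e <- list(stream = stream, from = from, to = to, w = 0L, blocked = FALSE, gkey = NULL)
  }
  if (e$blocked) {
    trace_event(m, "warn", sprintf("adjust on BLOCKED %s->%s ignored", from, to))
    return(invisible(m))
  }
  e$w <- max(0L, e$w + as.integer(delta))
  m$weights[[key]] <- e
  trace_event(m, "weight", sprintf("%s->%s = %d", from, to, e$w))
  invisible(m)
}

#' Dump the weight table
#'
#' @param m a model.
#' @return a data.frame with columns stream, sender, receiver, weight
#'   (weight is `"BLOCKED"` for blocked entries), ordered by key.
#' @export
weight_table <- function(m) {
  keys <- sort(ls(m$weights))
  rows <- lapply(keys, function(k) {
    e <- m$weights[[k]]
    data.frame(stream = e$stream, sender = e$from, receiver = e$to,
               weight = if (e$blocked) BLOCKED else as.character(e$w),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

## ---- firing and signalling -------------------------------------------------

active_instances <- function(m) {
  Filter(function(i) i$cycle <= m$cycle && m$cycle < i$cycle + i$ttl, m$instances)
}

find_active <- function(m, name) {
  for (i in rev(active_instances(m))) if (i$name == name) return(i)
  NULL
}

#' Activate a thread instance
#'
#' Fires `target` with the given binding (or an explicit ground `term`);
#' the instance becomes active this cycle and the event is logged. Firing
#' is idempotent within a cycle for an identical (template, instance) pair.
#' Firing an effector records an action.
#'
#' @param m model.
#' @param target template name.
#' @param binding substitution applied to the template pattern.
#' @param term optional explicit instance term (overrides `binding`).
#' @return the instance id, invisibly (`NA` if suppressed as a duplicate).
#' @export
vm_fire <- function(m, target, binding = list(), term = NULL) {
  tmpl <- m$templates[[target]]
  if (is.null(tmpl)) stop(sprintf("unknown template '%s'", target))
  inst <- if (is.null(term)) subst_apply(binding, tmpl$pattern) else term
  txt <- format_term(inst)
  for (i in m$instances) {
    if (i$name == target && i$cycle == m$cycle && i$text == txt) return(invisible(NA_integer_))
  }
  id <- new_id(m)
  m$instances[[length(m$instances) + 1L]] <-
    list(id = id, name = target, term = inst, text = txt,
         cycle = m$cycle, ttl = tmpl$ttl)
  trace_event(m, "fire", sprintf("%s %s", target, txt))
  if (tmpl$kind == "effector") {
    m$actions[[length(m$actions) + 1L]] <- list(cycle = m$cycle, term = inst)
    trace_event(m, "action", txt)
  }
  invisible(id)
}

#' Post a signal from an active sender
#'
#' Appends a signal to the queue, stamped with the current cycle. Sends
#' from a template with no active instance are rejected as a protocol
#' error (logged, not thrown). Delivery is a separate, weight-gated step.
#'
#' @param m model.
#' @param from sender template name (must have an active instance).
#' @param to receiver template name (same stream as the sender).
#' @param payload the ground term carried by the signal.
#' @return `TRUE` if queued, `FALSE` if rejected.
#' @export
vm_send <- function(m, from, to, payload) {
  if (is.null(find_active(m, from))) {
    trace_event(m, "warn", sprintf("send from dormant '%s' rejected", from))
    return(FALSE)
  }
  m$queue[[length(m$queue) + 1L]] <-
    list(id = new_id(m), from = from, to = to, payload = payload, cycle = m$cycle)
  trace_event(m, "send", sprintf("%s->%s %s", from, to, format_term(payload)))
  TRUE
}

#' Deliver queued signals to a receiver
#'
#' Consumes, in FIFO order, every queued signal addressed to `receiver`
#' whose sender->receiver weight (with any active short-term potentiation)
#' meets the threshold and is not `BLOCKED`; each delivered payload fires
#' the receiver. Sub-threshold signals stay queued until they expire;
#' signals on a blocked pathway are never delivered.
#'
#' @param m model.
#' @param receiver receiver template name.
#' @return list of delivered payload terms.
#' @export
vm_deliver <- function(m, receiver) {
  tmpl <- m$templates[[receiver]]
  if (is.null(tmpl)) stop(sprintf("unknown template '%s'", receiver))
  delivered <- list()
  keep <- list()
  for (sig in m$queue) {
    if (sig$to != receiver) { keep[[length(keep) + 1L]] <- sig; next }
    sender <- m$templates[[sig$from]]
    if (!identical(sender$stream, tmpl$stream)) {  # streams isolate communication
      trace_event(m, "warn", sprintf("cross-stream signal %s->%s dropped", sig$from, sig$to))
      next
    }
    g <- gate_check(m, tmpl$stream, sig$from, sig$to, sig$payload)
    if (!g$open) { if (!g$blocked) keep[[length(keep) + 1L]] <- sig; next }
    s <- unify(tmpl$pattern, g$payload)
    if (is.null(s)) {
      trace_event(m, "warn", sprintf("payload %s does not match %s", format_term(g$payload), receiver))
      next
    }
    trace_event(m, "deliver", sprintf("%s->%s %s", sig$from, sig$to, format_term(g$payload)))
    vm_fire(m, receiver, term = subst_apply(s, g$payload))
    delivered[[length(delivered) + 1L]] <- g$payload
  }
  m$queue <- keep
  delivered
}

drain_deliveries <- function(m) {
  n <- 0L
  repeat {
    receivers <- unique(vapply(m$queue, function(s) s$to, ""))
    if (length(receivers) == 0L) break
    got <- 0L
    for (r in receivers) got <- got + length(vm_deliver(m, r))
    n <- n + got
    if (got == 0L) break
  }
  n
}

## ---- join / merge coincidence ---------------------------------------------

register_protocol <- function(m, pid, stream, q, r) {
  m$protocols[[pid]] <- list(stream = stream, q = q, r = r)
  invisible(m)
}

potentiate <- function(m, pid, payload) {
  p <- m$protocols[[pid]]
  key <- wkey(p$stream, p$q, p$r)
  e <- m$weights[[key]]
  if (is.null(e)) e <- list(stream = p$stream, from = p$q, to = p$r, w = 0L,
                            blocked = FALSE, gkey = NULL)
  if (e$blocked) {
    trace_event(m, "warn", sprintf("ltp on BLOCKED %s->%s ignored", p$q, p$r))
    return(invisible(m))
  }
  if (m$config$mode == "weak") {
    if (is.null(e$gkey)) {
      if (!is_ground(payload)) {
        trace_event(m, "warn", sprintf("weak ltp %s->%s: non-ground instance refused", p$q, p$r))
        return(invisible(m))
      }
      e$gkey <- payload  # the pathway binds to its first ground instantiation
    } else if (!term_equal(e$gkey, payload)) {
      trace_event(m, "warn", sprintf("weak ltp %s->%s: rebinding to %s refused",
                                     p$q, p$r, format_term(payload)))
      m$weights[[key]] <- e
      return(invisible(m))
    }
  }
  e$w <- e$w + 1L
  m$weights[[key]] <- e
  trace_event(m, "weight", sprintf("%s->%s = %d [ltp]", p$q, p$r, e$w))
  invisible(m)
}

#' Register a coincidence join (the ltp side)
#'
#' The ltp thread spawned by the protocol trigger registers a join and
#' waits for a merge posted by the to-be-potentiated sender. If an unused
#' merge for the same protocol lies within the coincidence window the pair
#' synchronizes immediately and the pathway is potentiated.
#'
#' @param m model.
#' @param pid protocol identifier (registered at compile time).
#' @return `TRUE` if the join synchronized with a merge.
#' @export
vm_join <- function(m, pid) {
  w <- m$config$coincidence_window
  for (k in seq_along(m$merges)) {
    mg <- m$merges[[k]]
    if (mg$pid == pid && !mg$used && abs(m$cycle - mg$cycle) <= w) {
      m$merges[[k]]$used <- TRUE
      trace_event(m, "ltp", sprintf("coincidence %s", pid))
      potentiate(m, pid, mg$payload)
      return(TRUE)
    }
  }
  m$joins[[length(m$joins) + 1L]] <- list(pid = pid, cycle = m$cycle, used = FALSE)
  FALSE
}

#' Post a merge signal (the sender side)
#'
#' @param m model.
#' @param pid protocol identifier.
#' @param payload the instantiated receiver pattern carried for weak-mode
#'   instance binding.
#' @return `TRUE` if the merge synchronized with a pending join.
#' @export
vm_merge <- function(m, pid, payload) {
  w <- m$config$coincidence_window
  for (k in seq_along(m$joins)) {
    jn <- m$joins[[k]]
    if (jn$pid == pid && !jn$used && abs(m$cycle - jn$cycle) <= w) {
      m$joins[[k]]$used <- TRUE
      trace_event(m, "ltp", sprintf("coincidence %s", pid))
      potentiate(m, pid, payload)
      return(TRUE)
    }
  }
  m$merges[[length(m$merges) + 1L]] <- list(pid = pid, payload = payload,
                                            cycle = m$cycle, used = FALSE)
  FALSE
}

#' Did a join and a merge coincide?
#'
#' Convenience synchronization primitive: registers a join for `pid` at the
#' current cycle and reports whether a merge posted by the partner thread
#' lies within `window` cycles; the merge is consumed on success and each
#' merge satisfies at most one join (FIFO priority).
#'
#' @param m model.
#' @param pid protocol identifier.
#' @param window optional override of the configured coincidence window.
#' @return `TRUE` or `FALSE`.
#' @export
join_merge <- function(m, pid, window = NULL) {
  if (!is.null(window)) {
    old <- m$config$coincidence_window
    m$config$coincidence_window <- as.integer(window)
    on.exit(m$config$coincidence_window <- old)
  }
  vm_join(m, pid)
}

prune_coincidence <- function(m) {
  w <- m$config$coincidence_window
  m$joins <- Filter(function(j) !j$used && m$cycle - j$cycle <= w, m$joins)
  m$merges <- Filter(function(g) !g$used && m$cycle - g$cycle <= w, m$merges)
  invisible(m)
}

## ---- plasticity protocols --------------------------------------------------

#' Short-term potentiation
#'
#' Raises the pathway to the delivery threshold for `duration` cycles
#' (current cycle included), after which the stored weight applies again.
#' STP on a blocked edge is a logged no-op.
#'
#' @inheritParams weight_init
#' @param duration number of cycles the pathway stays open.
#' @return the model, invisibly.
#' @export
stp_open <- function(m, stream, from, to, duration = NULL) {
  if (is.null(duration)) duration <- m$config$stp_duration
  key <- wkey(stream, from, to)
  e <- m$weights[[key]]
  if (!is.null(e) && e$blocked) {
    trace_event(m, "warn", sprintf("stp on BLOCKED %s->%s ignored", from, to))
    return(invisible(m))
  }
  m$stp[[length(m$stp) + 1L]] <- list(key = key, until = m$cycle + as.integer(duration) - 1L)
  trace_event(m, "stp", sprintf("%s->%s open for %d", from, to, as.integer(duration)))
  invisible(m)
}

#' Long-term depression
#'
#' @inheritParams weight_init
#' @return the model, invisibly.
#' @export
ltd <- function(m, stream, from, to) adjust_weight(m, stream, from, to, -1L)

#' Long-term blocking
#'
#' Permanently closes a pathway; `BLOCKED` is absorbing and no later
#' potentiation, depression or STP restores the edge. Models the
#' extinction of a futile action (a box found empty is not reopened).
#'
#' @inheritParams weight_init
#' @return the model, invisibly.
#' @export
ltb <- function(m, stream, from, to) {
  key <- wkey(stream, from, to)
  e <- m$weights[[key]]
  if (is.null(e)) e <- list(stream = stream, from = from, to = to, w = 0L,
                            blocked = FALSE, gkey = NULL)
  e$blocked <- TRUE
  m$weights[[key]] <- e
  trace_event(m, "weight", sprintf("%s->%s = BLOCKED", from, to))
  invisible(m)
}

#' Long-term storage
#'
#' Appends a ground trace to the associative store (rendered `{P}` in
#' traces). Traces never decay; retrieval is newest-first.
#'
#' @param m model.
#' @param trace_term a ground term.
#' @return the model, invisibly.
#' @export
lts <- function(m, trace_term) {
  if (!is_ground(trace_term)) {
    trace_event(m, "warn", sprintf("lts of non-ground %s refused", format_term(trace_term)))
    stop("lts requires a ground trace")
  }
  m$store <- c(list(list(term = trace_term, cycle = m$cycle)), m$store)
  trace_event(m, "store", sprintf("{%s}", format_term(trace_term)))
  invisible(m)
}

#' Long-term retrieval
#'
#' The associative-memory read: fired by an active cue thread `q`, it scans
#' the store newest-first for a trace unifying with `p_pattern`; on a hit
#' the q->r pathway is potentiated and `r` is fired with the retrieval
#' bindings applied to `r_payload`. Retrieval is non-destructive; a
#' `BLOCKED` q->r edge suppresses both effects. An empty or non-matching
#' store is a silent no-op.
#'
#' @param m model.
#' @param p_pattern pattern matched against stored traces.
#' @param q cue template name (must be active).
#' @param r recall template name.
#' @param s substitution from the current deduction (cue bindings).
#' @param r_payload term fired on `r` (defaults to `r`'s pattern).
#' @return the retrieval substitution, or `NULL` when nothing fired.
#' @export
ltr <- function(m, p_pattern, q, r, s = list(), r_payload = NULL) {
  qt <- m$templates[[q]]; rt <- m$templates[[r]]
  if (is.null(find_active(m, q))) return(NULL)
  key <- wkey(qt$stream, q, r)
  e <- m$weights[[key]]
  if (!is.null(e) && e$blocked) {
    trace_event(m, "warn", sprintf("ltr on BLOCKED %s->%s ignored", q, r))
    return(NULL)
  }
  pat <- subst_apply(s, p_pattern)
  for (entry in m$store) {
    s2 <- unify(pat, entry$term, s)
    if (!is.null(s2)) {
      trace_event(m, "retrieve", sprintf("{%s}", format_term(entry$term)))
      adjust_weight(m, qt$stream, q, r, 1L)
      payload <- subst_apply(s2, if (is.null(r_payload)) rt$pattern else r_payload)
      vm_fire(m, r, term = payload)
      return(s2)
    }
  }
  NULL
}

#' Short-term FIFO memory
#'
#' Per-tag first-in-first-out queues of ground terms (rendered `<t>`),
#' used to recall a sequence of displacements in order. `stm_pop` on an
#' empty queue returns `NULL` (an empty marker, not an error); entries
#' persist until consumed.
#'
#' @param m model.
#' @param tag queue name.
#' @param term a ground term (push only).
#' @return `stm_push`: the model, invisibly. `stm_pop`: the oldest term or
#'   `NULL`. `stm_peek`: the queue contents as a list.
#' @export
stm_push <- function(m, tag, term) {
  if (!is_ground(term)) stop("stm_push requires a ground term")
  q <- m$stm[[tag]]
  if (is.null(q)) q <- list()
  m$stm[[tag]] <- c(q, list(term))
  trace_event(m, "stm", sprintf("<%s> push %s", tag, format_term(term)))
  invisible(m)
}

#' @rdname stm_push
#' @export
stm_pop <- function(m, tag) {
  q <- m$stm[[tag]]
  if (is.null(q) || length(q) == 0L) {
    trace_event(m, "stm", sprintf("<%s> pop empty", tag))
    return(NULL)
  }
  out <- q[[1L]]
  m$stm[[tag]] <- q[-1L]
  trace_event(m, "stm", sprintf("<%s> pop %s", tag, format_term(out)))
  out
}

#' @rdname stm_push
#' @export
stm_peek <- function(m, tag) {
  q <- m$stm[[tag]]
  if (is.null(q)) list() else q
}
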