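# The sense-react virtual machine realizing run: I x L -> L x O.
# Each cycle senses the stimulus batch, then reacts: contextual deduction
# (ist) over a snapshot of the active thread instances, ordered application
# of the deduced instructions, and weight-gated delivery of queued signals,
# repeated to fixpoint within the cycle. Everything is deterministic: there
# is no randomness anywhere in the machine.

#' Contextual deduction
#'
#' The "is true" predicate: returns every (implication, substitution) pair
#' whose guards unify conjunctively with the current facts, in rule-base
#' order and then fact-recency order (newest facts first). Guard slots of a
#' single instantiation consume distinct facts, so one fact supports at
#' most one slot per deduction. Facts are the active thread instances;
#' `facts` may be given directly as a list of `list(id, name, term)` rows,
#' which is how the brute-force oracle exercises the same contract.
#'
#' @param m a compiled model, or a plain fact list.
#' @param rulebase optional rule base (defaults to the model's).
#' @return list of deductions `list(impl, s, ids)`.
#' @export
ist <- function(m, rulebase = NULL) {
  if (inherits(m, "vcog_model")) {
    facts <- lapply(active_instances(m), function(i) list(id = i$id, name = i$name, term = i$term))
    if (is.null(rulebase)) rulebase <- m$rulebase
  } else {
    facts <- m
    if (is.null(rulebase)) stop("a rule base is required when facts are given directly")
  }
  # newest first
  if (length(facts) > 1L) {
    facts <- facts[order(vapply(facts, function(f) f$id, 0L), decreasing = TRUE)]
  }
  out <- list()
  solve <- function(guards, gi, s, ids) {
    if (gi > length(guards)) return(list(list(s = s, ids = ids)))
    res <- list()
    g <- guards[[gi]]
    for (f in facts) {
      if (f$name != g$name || f$id %in% ids) next
      s2 <- unify(g$pat, f$term, s)
      if (!is.null(s2)) res <- c(res, solve(guards, gi + 1L, s2, c(ids, f$id)))
    }
    res
  }
  for (im in rulebase) {
    for (sol in solve(im$guards, 1L, list(), integer(0))) {
      out[[length(out) + 1L]] <- list(impl = im, s = sol$s, ids = sol$ids)
    }
  }
  out
}

apply_ops <- function(m, im, s) {
  effect <- FALSE
  for (op in im$ops) {
    eff <- switch(op$type,
      send = {
        vm_send(m, op$from, op$to, subst_apply(s, op$payload))
      },
      conj_fire = {
        open <- TRUE
        frozen <- NULL
        for (g in op$gates) {
          gc <- gate_check(m, g$stream, g$from, g$to, NULL)
          if (!gc$open) { open <- FALSE; break }
          e <- m$weights[[wkey(g$stream, g$from, g$to)]]
          if (!is.null(e$gkey)) frozen <- e$gkey
        }
        if (open) {
          payload <- if (is.null(frozen)) subst_apply(s, op$payload) else frozen
          if (!is_ground(payload)) {
            trace_event(m, "warn", sprintf("non-ground fire of %s suppressed", op$node))
            FALSE
          } else {
            !is.na(vm_fire(m, op$node, term = payload))
          }
        } else FALSE
      },
      ltp_merge = { vm_merge(m, op$pid, subst_apply(s, op$pat)); TRUE },
      ltp_join = { vm_join(m, op$pid); TRUE },
      stp = {
        stp_open(m, op$stream, op$from, op$to,
                 if (is.na(op$dur)) NULL else op$dur)
        TRUE
      },
      ltd = { ltd(m, op$stream, op$from, op$to); TRUE },
      ltb = { ltb(m, op$stream, op$from, op$to); TRUE },
      lts = {
        term <- subst_apply(s, op$pat)
        if (is_ground(term)) { lts(m, term); TRUE } else {
          trace_event(m, "warn", sprintf("lts of non-ground %s suppressed", format_term(term)))
          FALSE
        }
      },
      ltr = {
        !is.null(ltr(m, op$pat, op$q, op$r, s = s, r_payload = op$payload))
      },
      pop_send = {
        popped <- stm_pop(m, op$tag)
        if (is.null(popped)) FALSE else {
          s2 <- unify(op$pop_pat, popped, s)
          if (is.null(s2)) {
            trace_event(m, "warn", sprintf("<%s> entry %s does not match pop pattern",
                                           op$tag, format_term(popped)))
            FALSE
          } else {
            vm_send(m, op$from, op$to, subst_apply(s2, op$payload))
          }
        }
      },
      stm_push = {
        term <- subst_apply(s, op$pat)
        if (is_ground(term)) { stm_push(m, op$tag, term); TRUE } else FALSE
      },
      stop(sprintf("unknown op '%s'", op$type))
    )
    effect <- effect || isTRUE(eff)
  }
  effect
}

subst_sig <- function(s) {
  if (length(s) == 0L) return("")
  ks <- sort(names(s))
  paste(ks, vapply(s[ks], format_term, ""), sep = "=", collapse = ";")
}

#' Capture one stimulus
#'
#' Fires every sensor template whose pattern unifies with the (ground)
#' input; non-matching stimuli are dropped and logged.
#'
#' @param m model.
#' @param input a ground stimulus term.
#' @return the model, invisibly.
#' @export
sense <- function(m, input) {
  if (!is_ground(input)) stop("stimuli must be ground")
  trace_event(m, "stimulus", format_term(input))
  hit <- FALSE
  for (tmpl in m$templates) {
    if (tmpl$kind != "sensor") next
    s <- unify(tmpl$pattern, input)
    if (!is.null(s)) {
      vm_fire(m, tmpl$name, term = input)
      hit <- TRUE
    }
  }
  if (!hit) {
    m$dropped[[length(m$dropped) + 1L]] <- list(cycle = m$cycle, term = input)
    trace_event(m, "drop", format_term(input))
  }
  invisible(m)
}

#' Deduce and apply instructions for the current cycle
#'
#' Repeats deduce-apply-deliver passes until a fixpoint: each pass computes
#' `ist` over the pre-pass snapshot of instances, applies the deduced
#' instructions in order (each (implication, facts, binding) triple at most
#' once per run; choice groups resolve to their first applying member per
#' cycle), then drains weight-gated deliveries. A pass limit guards
#' against pathological circuits; exceeding it flags truncation in the
#' trace rather than raising.
#'
#' @param m model.
#' @return number of instruction applications this cycle, invisibly.
#' @export
react <- function(m) {
  total <- 0L
  pass <- 0L
  repeat {
    pass <- pass + 1L
    if (pass > m$config$pass_limit) {
      m$truncated <- TRUE
      trace_event(m, "warn", "react pass limit reached; cycle truncated")
      break
    }
    deds <- ist(m)
    applied_now <- 0L
    for (d in deds) {
      key <- paste(d$impl$id, paste(d$ids, collapse = ","), subst_sig(d$s), sep = "|")
      if (!is.null(m$applied[[key]])) next
      if (!is.null(d$impl$choice)) {
        ck <- paste(d$impl$choice, m$cycle, sep = "|")
        if (!is.null(m$choice_done[[ck]])) next
      }
      if (apply_ops(m, d$impl, d$s)) {
        m$applied[[key]] <- TRUE
        if (!is.null(d$impl$choice)) m$choice_done[[paste(d$impl$choice, m$cycle, sep = "|")]] <- TRUE
        applied_now <- applied_now + 1L
      }
    }
    ndel <- drain_deliveries(m)
    total <- total + applied_now
    if (applied_now == 0L && ndel == 0L) break
  }
  invisible(total)
}

end_cycle <- function(m) {
  ttl <- m$config$signal_ttl
  m$queue <- Filter(function(sig) (m$cycle + 1L) - sig$cycle <= ttl, m$queue)
  prune_coincidence(m)
  m$stp <- Filter(function(s) s$until > m$cycle, m$stp)
  m$instances <- Filter(function(i) i$cycle + i$ttl > m$cycle + 1L, m$instances)
  m$cycle <- m$cycle + 1L
  invisible(m)
}

schedule_stimulus <- function(m, cycle, term) {
  key <- as.character(cycle)
  m$pending[[key]] <- c(m$pending[[key]], list(term))
  invisible(m)
}

#' Run the sense-react loop
#'
#' Executes `loop { sense; react }` over a timed stimulus schedule until
#' the schedule is exhausted and the model quiescent (no queued signals,
#' no pending stimuli, and a react pass that applied nothing), or until
#' `max_cycles`. There is no designated final state: whatever state the
#' machine is in is acceptable.
#'
#' @param m a compiled model.
#' @param stimuli list of `list(cycle, term)` records (term may be a string
#'   in literal syntax).
#' @param max_cycles hard cycle bound; reaching it with a non-quiescent
#'   model flags truncation in the trace, never an error.
#' @param on_actions optional callback `function(m, actions, cycle)` invoked
#'   with the actions emitted each cycle (the world feedback hook); it may
#'   schedule further stimuli via [schedule_stimulus()].
#' @return the model, invisibly; actions and trace are in `m$actions`,
#'   `m$trace`.
#' @export
run_vm <- function(m, stimuli = list(), max_cycles = 50L, on_actions = NULL) {
  sched <- list()
  last_scripted <- 0L
  for (st in stimuli) {
    term <- if (is.character(st$term)) vt(st$term) else st$term
    key <- as.character(st$cycle)
    sched[[key]] <- c(sched[[key]], list(term))
    last_scripted <- max(last_scripted, st$cycle)
  }
  repeat {
    t <- m$cycle
    if (t > max_cycles) {
      m$truncated <- TRUE
      trace_event(m, "warn", "cycle limit reached")
      break
    }
    batch <- c(sched[[as.character(t)]], m$pending[[as.character(t)]])
    m$pending[[as.character(t)]] <- NULL
    n_before <- length(m$actions)
    for (input in batch) sense(m, input)
    applied <- react(m)
    if (!is.null(on_actions)) {
      acts <- if (length(m$actions) > n_before) m$actions[(n_before + 1L):length(m$actions)] else list()
      on_actions(m, acts, t)
    }
    pending_left <- length(m$pending) > 0L && any(vapply(m$pending, length, 0L) > 0L)
    quiescent <- applied == 0L && length(m$queue) == 0L && !pending_left
    end_cycle(m)
    if (t >= last_scripted && quiescent) break
  }
  invisible(m)
}

## ---- traces ----------------------------------------------------------------

#' Extract the trace as a data frame
#'
#' @param m model.
#' @return data.frame with columns cycle, kind, text.
#' @export
get_trace <- function(m) {
  data.frame(
    cycle = vapply(m$trace, function(e) e$cycle, 0L),
    kind = vapply(m$trace, function(e) e$kind, ""),
    text = vapply(m$trace, function(e) e$text, ""),
    stringsAsFactors = FALSE
  )
}

#' Extract emitted actions
#'
#' @param m model.
#' @return data.frame with columns cycle, action (literal syntax).
#' @export
get_actions <- function(m) {
  data.frame(
    cycle = vapply(m$actions, function(a) a$cycle, 0L),
    action = vapply(m$actions, function(a) format_term(a$term), ""),
    stringsAsFactors = FALSE
  )
}

#' Canonical trace rendering
#'
#' One line per event, `cycle<TAB>kind<TAB>text`, with freshly generated
#' variable names renamed to `v1, v2, ...` in order of first appearance so
#' that traces from independent runs are comparable.
#'
#' @param trace a data.frame from [get_trace()] or a model.
#' @return character vector of lines.
#' @export
format_trace <- function(trace) {
  if (inherits(trace, "vcog_model")) trace <- get_trace(trace)
  lines <- sprintf("%d\t%s\t%s", trace$cycle, trace$kind, trace$text)
  canon_lines(lines)
}

canon_lines <- function(lines) {
  # rename fresh suffixes (X_G12, _34) to v1, v2... by first appearance
  map <- new.env(parent = emptyenv())
  n <- 0L
  one <- function(line) {
    m <- gregexpr("[A-Za-z][A-Za-z0-9]*_G[0-9]+|_[0-9]+", line)[[1]]
    if (m[[1]] == -1L) return(line)
    parts <- regmatches(line, list(m))[[1]]
    for (p in unique(parts)) {
      if (is.null(map[[p]])) {
        n <<- n + 1L
        map[[p]] <- paste0("v", n)
      }
    }
    for (p in unique(parts)) line <- gsub(p, map[[p]], line, fixed = TRUE)
    line
  }
  vapply(lines, one, "", USE.NAMES = FALSE)
}

#' Compare two traces
#'
#' Compares canonical renderings and reports the first divergent event
#' with context, or equality. Traces differing only in generated fresh
#' variable names compare equal.
#'
#' @param a,b traces (data frames or models).
#' @return list with `equal`; when unequal also `index`, `a`, `b`.
#' @export
compare_traces <- function(a, b) {
  la <- format_trace(a)
  lb <- format_trace(b)
  n <- max(length(la), length(lb))
  for (i in seq_len(n)) {
    xa <- if (i <= length(la)) la[[i]] else "<end of trace>"
    xb <- if (i <= length(lb)) lb[[i]] else "<end of trace>"
    if (!identical(xa, xb)) {
      ctx <- function(l) l[max(1L, i - 2L):min(length(l), i)]
      return(list(equal = FALSE, index = i, a = xa, b = xb,
                  context_a = ctx(la), context_b = ctx(lb)))
    }
  }
  list(equal = TRUE)
}
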