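# Circuit compiler: parse the line-oriented .vcir DSL, validate the circuit
# graph, and compile it into an ordered rule base of virtual-code
# implications (guard patterns => virtual-machine instructions) consumed by
# contextual deduction.
#
# DSL (one declaration per line, '#' comments):
#   circuit <name>
#   stream <id>
#   node <kind> <stream> <name> <pattern> [ttl=N] [plasticity=lts]
#                                         [plasticity=push:<tag>]
#   edge <type> <from> <to> [w=N] [payload=<term>] [as=<term>]
#        [plasticity=<kind>[:<arg>[:<arg>]]] [pop=<tag>:<pattern>]
#        [choice=<group>]
#   edge modulation <node> <from>><to> [plasticity=<ltp|ltd|ltb>]
#
# Edge types: synapse (->=>-), div (signal splitting), choice (converging
# alternatives, first declared match wins), conj (* converging signals all
# required, grouped by target node), modulation (/|\ attaching a plasticity
# protocol onto an existing synapse). Plasticity kinds on edges:
# stp[:trigger[:duration]], ltp:trigger, ltd:trigger, ltb:trigger,
# ltr:<store-pattern>; on nodes: lts, push:<tag>. Patterns contain no
# whitespace. The weak/strong LTP mode is a run-level configuration, not a
# circuit property.

parse_attrs <- function(tokens, line, errors) {
  at <- list(plasticity = list())
  for (tok in tokens) {
    if (!grepl("=", tok, fixed = TRUE)) {
      errors(sprintf("line %d: malformed attribute '%s'", line, tok))
      next
    }
    key <- sub("=.*$", "", tok)
    val <- sub("^[^=]*=", "", tok)
    if (key == "plasticity") {
      at$plasticity <- c(at$plasticity, list(strsplit(val, ":", fixed = TRUE)[[1]]))
    } else {
      at[[key]] <- val
    }
  }
  at
}

try_term <- function(text, line, errors) {
  tryCatch(vt(text), error = function(e) {
    errors(sprintf("line %d: %s", line, conditionMessage(e)))
    NULL
  })
}

#' Parse a circuit specification
#'
#' Parses the `.vcir` text DSL into a circuit spec. Syntax problems are
#' collected (with line numbers) in the spec's `errors` field rather than
#' thrown; [validate_circuit()] performs the structural checks.
#'
#' @param text the circuit source, as a single string or character vector
#'   of lines.
#' @return a list of class `vcog_circuit` with fields `name`, `streams`,
#'   `nodes`, `edges`, `errors`.
#' @export
parse_circuit <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  errs <- character(0)
  errors <- function(msg) errs <<- c(errs, msg)
  spec <- list(name = NULL, streams = character(0), nodes = list(), edges = list())
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln]])
    raw <- trimws(raw)
    if (raw == "") next
    toks <- strsplit(raw, "[[:space:]]+")[[1]]
    head <- toks[[1]]
    if (head == "circuit") {
      spec$name <- toks[[2]]
    } else if (head == "stream") {
      spec$streams <- c(spec$streams, toks[[2]])
    } else if (head == "node") {
      if (length(toks) < 5L) { errors(sprintf("line %d: node needs kind stream name pattern", ln)); next }
      kind <- toks[[2]]
      if (!kind %in% c("sensor", "effector", "internal", "plasticity")) {
        errors(sprintf("line %d: unknown node kind '%s'", ln, kind)); next
      }
      pat <- try_term(toks[[5]], ln, errors)
      if (is.null(pat)) next
      at <- parse_attrs(toks[-(1:5)], ln, errors)
      nd <- list(name = toks[[4]], kind = kind, stream = toks[[3]], pattern = pat,
                 ttl = if (is.null(at$ttl)) 1L else as.integer(at$ttl),
                 plasticity = at$plasticity, line = ln)
      if (!is.null(spec$nodes[[nd$name]])) errors(sprintf("line %d: duplicate node '%s'", ln, nd$name))
      spec$nodes[[nd$name]] <- nd
    } else if (head == "edge") {
      if (length(toks) < 4L) { errors(sprintf("line %d: edge needs type from to", ln)); next }
      type <- toks[[2]]
      if (!type %in% c("synapse", "conj", "div", "choice", "modulation")) {
        errors(sprintf("line %d: malformed connector '%s'", ln, type)); next
      }
      at <- parse_attrs(toks[-(1:4)], ln, errors)
      ed <- list(idx = length(spec$edges) + 1L, type = type,
                 from = toks[[3]], to = toks[[4]],
                 w = if (is.null(at$w)) 1L else as.integer(at$w),
                 payload = if (is.null(at$payload)) NULL else try_term(at$payload, ln, errors),
                 as = if (is.null(at$as)) NULL else try_term(at$as, ln, errors),
                 pop = at$pop, choice = at$choice,
                 plasticity = at$plasticity, line = ln)
      spec$edges[[length(spec$edges) + 1L]] <- ed
    } else {
      errors(sprintf("line %d: unknown declaration '%s'", ln, head))
    }
  }
  if (length(spec$nodes) == 0L) errors("no nodes declared")
  spec$errors <- errs
  class(spec) <- "vcog_circuit"
  spec
}

#' Validate a parsed circuit
#'
#' Checks the structural invariants: every edge endpoint is a declared
#' node, endpoints of a weighted edge share a stream, modulation attaches
#' to an existing synapse, conjunction targets have at least two in-edges,
#' divergence sources at least two out-edges, each node belongs to a
#' declared stream, and every pattern variable reaching an instruction is
#' bound by a guard (range restriction).
#'
#' @param spec a `vcog_circuit`.
#' @return character vector of violations; empty when the circuit is valid.
#' @export
validate_circuit <- function(spec) {
  rep <- spec$errors
  nodes <- spec$nodes
  syn_ids <- vapply(Filter(function(e) e$type %in% c("synapse", "div", "choice"), spec$edges),
                    function(e) paste0(e$from, ">", e$to), "")
  for (nd in nodes) {
    if (!nd$stream %in% spec$streams)
      rep <- c(rep, sprintf("line %d: node '%s' in undeclared stream '%s'", nd$line, nd$name, nd$stream))
    for (pl in nd$plasticity) {
      if (!pl[[1]] %in% c("lts", "push"))
        rep <- c(rep, sprintf("line %d: node plasticity '%s' unknown", nd$line, pl[[1]]))
    }
  }
  conj_in <- list(); div_out <- list()
  for (ed in spec$edges) {
    if (ed$type == "modulation") {
      if (is.null(nodes[[ed$from]]))
        rep <- c(rep, sprintf("line %d: modulation source '%s' undeclared", ed$line, ed$from))
      if (!ed$to %in% syn_ids)
        rep <- c(rep, sprintf("line %d: modulation on non-synapse '%s'", ed$line, ed$to))
      next
    }
    for (end in c(ed$from, ed$to)) {
      if (is.null(nodes[[end]]))
        rep <- c(rep, sprintf("line %d: edge endpoint '%s' undeclared", ed$line, end))
    }
    if (!is.null(nodes[[ed$from]]) && !is.null(nodes[[ed$to]]) &&
        !identical(nodes[[ed$from]]$stream, nodes[[ed$to]]$stream))
      rep <- c(rep, sprintf("line %d: edge %s->%s crosses streams", ed$line, ed$from, ed$to))
    if (ed$type == "conj") conj_in[[ed$to]] <- c(conj_in[[ed$to]], ed$from)
    if (ed$type == "div") div_out[[ed$from]] <- c(div_out[[ed$from]], ed$to)
    if (!is.null(ed$as) && !is.null(nodes[[ed$from]])) {
      if (is.null(unify(ed$as, freshen(nodes[[ed$from]]$pattern))))
        rep <- c(rep, sprintf("line %d: 'as' pattern does not match node '%s'", ed$line, ed$from))
    }
    for (pl in ed$plasticity) {
      kind <- pl[[1]]
      if (!kind %in% c("stp", "ltp", "ltd", "ltb", "ltr"))
        rep <- c(rep, sprintf("line %d: edge plasticity '%s' unknown", ed$line, kind))
      if (kind %in% c("ltp", "ltd", "ltb") && (length(pl) < 2L || is.null(nodes[[pl[[2]]]])))
        rep <- c(rep, sprintf("line %d: %s trigger undeclared", ed$line, kind))
    }
  }
  for (nm in names(conj_in)) {
    if (length(conj_in[[nm]]) < 2L)
      rep <- c(rep, sprintf("conjunction node '%s' has fewer than 2 in-edges", nm))
  }
  for (nm in names(div_out)) {
    if (length(div_out[[nm]]) < 2L)
      rep <- c(rep, sprintf("divergence source '%s' has fewer than 2 out-edges", nm))
  }
  rep
}

guard_pat <- function(spec, ed) if (is.null(ed$as)) spec$nodes[[ed$from]]$pattern else ed$as
payload_pat <- function(spec, ed) if (is.null(ed$payload)) spec$nodes[[ed$to]]$pattern else ed$payload

mk_impl <- function(key, guards, ops, choice = NULL, src = NULL) {
  list(id = NA_integer_, key = key, guards = guards, ops = ops, choice = choice, src = src)
}

#' Compile a circuit into a rule base
#'
#' Deterministically lowers a validated circuit into an ordered sequence of
#' implications. Each synapse yields a send implication guarded on its
#' sender's activation; a conjunction yields one implication guarded on all
#' its in-nodes (co-occurring within the same cycle, positions linked by
#' shared variables); divergence yields one implication per branch; choice
#' alternatives share a group resolved first-declared-first. Plasticity
#' annotations compile to protocol-spawning implications (merge posting on
#' the potentiated sender, join spawning on the trigger, LTD/LTB/STP on
#' their triggers, LTS/push on their nodes, LTR and STM-pop edges into
#' retrieval-driven firing).
#'
#' @param spec a parsed circuit.
#' @param model optionally, an existing model to load the rule base into.
#' @return a model of class `vcog_model` with templates, initial weights
#'   and the compiled rule base installed.
#' @export
compile_circuit <- function(spec, model = NULL) {
  viol <- validate_circuit(spec)
  if (length(viol) > 0L) stop(paste(c("invalid circuit:", viol), collapse = "\n  "))
  m <- if (is.null(model)) new_model() else model
  for (nd in spec$nodes) add_template(m, nd$name, nd$kind, nd$stream, nd$pattern, nd$ttl)

  # fold modulation edges into plasticity annotations on their target synapse
  edges <- Filter(function(e) e$type != "modulation", spec$edges)
  for (ed in spec$edges) {
    if (ed$type != "modulation") next
    tgt <- strsplit(ed$to, ">", fixed = TRUE)[[1]]
    kind <- if (length(ed$plasticity) > 0L) ed$plasticity[[1]][[1]] else "ltp"
    for (k in seq_along(edges)) {
      if (edges[[k]]$from == tgt[[1]] && edges[[k]]$to == tgt[[2]]) {
        edges[[k]]$plasticity <- c(edges[[k]]$plasticity, list(c(kind, ed$from)))
      }
    }
  }

  impls <- list()   # each with a numeric sort key: idx*10 + subpriority
  emit <- function(sortkey, impl) {
    impl$sort <- sortkey
    impls[[length(impls) + 1L]] <<- impl
  }

  # node-attached protocols (LTS storage, STM push)
  for (nd in spec$nodes) {
    for (pl in nd$plasticity) {
      if (pl[[1]] == "lts") {
        emit(nd$line * 10, mk_impl(paste0("lts:", nd$name),
          guards = list(list(name = nd$name, pat = nd$pattern)),
          ops = list(list(type = "lts", pat = nd$pattern)), src = nd$line))
      } else if (pl[[1]] == "push") {
        emit(nd$line * 10, mk_impl(paste0("push:", nd$name),
          guards = list(list(name = nd$name, pat = nd$pattern)),
          ops = list(list(type = "stm_push", tag = pl[[2]], pat = nd$pattern)), src = nd$line))
      }
    }
  }

  conj_groups <- list()  # target node -> list of edges, keyed for later emission
  for (ed in edges) {
    stream <- spec$nodes[[ed$from]]$stream
    weight_init(m, stream, ed$from, ed$to, ed$w)
    ltr_pat <- NULL
    for (pl in ed$plasticity) {
      kind <- pl[[1]]
      if (kind == "ltp") {
        pid <- sprintf("ltp:%s>%s", ed$from, ed$to)
        register_protocol(m, pid, stream, ed$from, ed$to)
        trig <- pl[[2]]
        emit(ed$line * 10 + 1, mk_impl(paste0("merge:", pid),
          guards = list(list(name = ed$from, pat = guard_pat(spec, ed))),
          ops = list(list(type = "ltp_merge", pid = pid, pat = payload_pat(spec, ed))),
          src = ed$line))
        emit(ed$line * 10 + 2, mk_impl(paste0("join:", pid, "<", trig),
          guards = list(list(name = trig, pat = spec$nodes[[trig]]$pattern)),
          ops = list(list(type = "ltp_join", pid = pid)), src = ed$line))
      } else if (kind == "stp") {
        trig <- if (length(pl) >= 2L && pl[[2]] != "") pl[[2]] else ed$from
        dur <- if (length(pl) >= 3L) as.integer(pl[[3]]) else NA_integer_
        emit(ed$line * 10 + 3, mk_impl(sprintf("stp:%s>%s<%s", ed$from, ed$to, trig),
          guards = list(list(name = trig, pat = spec$nodes[[trig]]$pattern)),
          ops = list(list(type = "stp", stream = stream, from = ed$from, to = ed$to, dur = dur)),
          src = ed$line))
      } else if (kind == "ltd") {
        emit(ed$line * 10 + 4, mk_impl(sprintf("ltd:%s>%s<%s", ed$from, ed$to, pl[[2]]),
          guards = list(list(name = pl[[2]], pat = spec$nodes[[pl[[2]]]]$pattern)),
          ops = list(list(type = "ltd", stream = stream, from = ed$from, to = ed$to)),
          src = ed$line))
      } else if (kind == "ltb") {
        emit(ed$line * 10 + 5, mk_impl(sprintf("ltb:%s>%s<%s", ed$from, ed$to, pl[[2]]),
          guards = list(list(name = pl[[2]], pat = spec$nodes[[pl[[2]]]]$pattern)),
          ops = list(list(type = "ltb", stream = stream, from = ed$from, to = ed$to)),
          src = ed$line))
      } else if (kind == "ltr") {
        ltr_pat <- vt(pl[[2]])
      }
    }
    if (ed$type == "conj") {
      conj_groups[[ed$to]] <- c(conj_groups[[ed$to]], list(ed))
      next
    }
    # transmission implication
    gp <- guard_pat(spec, ed)
    if (!is.null(ltr_pat)) {
      emit(ed$line * 10 + 6, mk_impl(sprintf("ltr:%s>%s", ed$from, ed$to),
        guards = list(list(name = ed$from, pat = gp)),
        ops = list(list(type = "ltr", pat = ltr_pat, q = ed$from, r = ed$to,
                        payload = payload_pat(spec, ed))),
        choice = ed$choice, src = ed$line))
    } else if (!is.null(ed$pop)) {
      pp <- strsplit(ed$pop, ":", fixed = TRUE)[[1]]
      emit(ed$line * 10 + 6, mk_impl(sprintf("pop:%s>%s", ed$from, ed$to),
        guards = list(list(name = ed$from, pat = gp)),
        ops = list(list(type = "pop_send", tag = pp[[1]], pop_pat = vt(pp[[2]]),
                        from = ed$from, to = ed$to, payload = payload_pat(spec, ed))),
        choice = ed$choice, src = ed$line))
    } else {
      emit(ed$line * 10 + 6, mk_impl(sprintf("send:%s>%s", ed$from, ed$to),
        guards = list(list(name = ed$from, pat = gp)),
        ops = list(list(type = "send", from = ed$from, to = ed$to,
                        payload = payload_pat(spec, ed))),
        choice = ed$choice, src = ed$line))
    }
  }

  for (nm in names(conj_groups)) {
    grp <- conj_groups[[nm]]
    last_line <- max(vapply(grp, function(e) e$line, 0L))
    guards <- lapply(grp, function(e) list(name = e$from, pat = guard_pat(spec, e)))
    gates <- lapply(grp, function(e) list(stream = spec$nodes[[e$from]]$stream,
                                          from = e$from, to = e$to))
    choice <- NULL
    for (e in grp) if (!is.null(e$choice)) choice <- e$choice
    emit(last_line * 10 + 6, mk_impl(paste0("conj:", nm),
      guards = guards,
      ops = list(list(type = "conj_fire", node = nm, payload = spec$nodes[[nm]]$pattern,
                      gates = gates)),
      choice = choice, src = last_line))
  }

  ord <- order(vapply(impls, function(i) i$sort, 0), method = "radix")
  rb <- impls[ord]
  for (k in seq_along(rb)) rb[[k]]$id <- k
  # range restriction: every variable an instruction uses must be bound by
  # the guards or by the op's own retrieval/pop pattern
  for (im in rb) {
    gv <- unique(unlist(lapply(im$guards, function(g) term_vars(g$pat))))
    for (op in im$ops) {
      extra <- character(0)
      if (op$type == "ltr") extra <- term_vars(op$pat)
      if (op$type == "pop_send") extra <- term_vars(op$pop_pat)
      pv <- if (!is.null(op$payload)) term_vars(op$payload)
            else if (!is.null(op$pat)) term_vars(op$pat) else character(0)
      free <- setdiff(pv, c(gv, extra))
      if (length(free) > 0L)
        stop(sprintf("range restriction violated in '%s': unbound %s",
                     im$key, paste(free, collapse = ",")))
    }
  }
  m$rulebase <- rb
  m$circuit <- spec
  m
}

#' Pretty-print a compiled rule base
#'
#' @param m a compiled model.
#' @return character vector, one numbered implication per line.
#' @export
format_rulebase <- function(m) {
  vapply(m$rulebase, function(im) {
    g <- paste(vapply(im$guards, function(x) sprintf("act(%s,%s)", x$name, format_term(x$pat)), ""),
               collapse = " & ")
    o <- paste(vapply(im$ops, function(op) {
      switch(op$type,
        send = sprintf("send(%s,%s,%s)", op$from, op$to, format_term(op$payload)),
        conj_fire = sprintf("fire(%s,%s)", op$node, format_term(op$payload)),
        ltp_merge = sprintf("merge(%s)", op$pid),
        ltp_join = sprintf("join(%s)", op$pid),
        stp = sprintf("stp(%s,%s)", op$from, op$to),
        ltd = sprintf("ltd(%s,%s)", op$from, op$to),
        ltb = sprintf("ltb(%s,%s)", op$from, op$to),
        lts = sprintf("lts(%s)", format_term(op$pat)),
        ltr = sprintf("ltr(%s,%s,%s)", format_term(op$pat), op$q, op$r),
        pop_send = sprintf("pop(%s,%s,%s)", op$tag, op$from, op$to),
        stm_push = sprintf("push(%s,%s)", op$tag, format_term(op$pat)),
        op$type)
    }, ""), collapse = "; ")
    sprintf("%2d. %s => %s", im$id, g, o)
  }, "")
}
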