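# The simulated experiments: circuit + scenario bundles with behavioral
# assertions, and the golden-trace regression surface.

circuit_dir <- function() {
  d <- system.file("extdata", "circuits", package = "virtcog")
  if (d == "" && dir.exists(file.path("inst", "extdata", "circuits")))
    d <- file.path("inst", "extdata", "circuits")
  d
}

circuit_aliases <- c(
  aplysia = "aplysia", operant = "operant",
  grasp = "grasp", substage1_2 = "grasp",
  track = "tracking", tracking = "tracking", substage3 = "tracking",
  anotb = "searching", searching = "searching", substage4 = "searching",
  obs55 = "obs55", substage5 = "obs55",
  obs64 = "obs64", substage6 = "obs64"
)

#' Build a named circuit
#'
#' Returns the parsed circuit spec for a simulated substage or demo
#' circuit. Each later sensory-motor circuit strictly extends the previous
#' one (the substage-4 circuit contains substage 3's nodes and edges as a
#' subgraph, and so on).
#'
#' @param id one of `aplysia`, `operant`, `grasp`/`substage1_2`,
#'   `tracking`/`substage3`, `searching`/`substage4`, `obs55`/`substage5`,
#'   `obs64`/`substage6` (experiment names `track`/`anotb` are accepted).
#' @return a `vcog_circuit`.
#' @export
build_circuit <- function(id) {
  file <- unname(circuit_aliases[id])
  if (is.na(file)) stop(sprintf("unknown circuit '%s'", id))
  path <- file.path(circuit_dir(), paste0(file, ".vcir"))
  parse_circuit(readLines(path))
}

experiment_registry <- function() {
  list(
    aplysia = list(circuit = "aplysia", config = list(mode = "weak"),
                   scenario = function(p) make_scenario("aplysia", p),
                   max_cycles = 20L,
                   assertions = list(
                     list(type = "before", upto = 2L, absent = "motor(X)"),
                     list(type = "present", pat = "motor(cs)", after = 6L),
                     list(type = "present", pat = "motor(us)"))),
    operant = list(circuit = "operant", config = list(mode = "strong"),
                   scenario = function(p) make_scenario("operant", p),
                   max_cycles = 12L,
                   assertions = list(list(type = "present", pat = "accept(I)"))),
    grasp = list(circuit = "grasp", config = list(),
                 scenario = function(p) make_scenario("grasp", p),
                 max_cycles = 8L,
                 assertions = list(list(type = "present", pat = "grasp(obj(P,X))"))),
    track = list(circuit = "tracking", config = list(),
                 scenario = function(p) make_scenario("track", p),
                 max_cycles = 10L,
                 assertions = list(list(type = "present", pat = "grasp(obj(toy,3))"))),
    anotb = list(circuit = "searching", config = list(mode = "weak"),
                 scenario = function(p) make_scenario("anotb", p),
                 max_cycles = 14L,
                 assertions = list(
                   list(type = "order", pats = c("look(obj(s1,3))", "search(T)",
                                                 "look(obj(s2,5))", "search(T)")))),
    obs55 = list(circuit = "obs55", config = list(mode = "strong", coincidence_window = 8L),
                 scenario = function(p) make_scenario("obs55", p),
                 max_cycles = 60L,
                 assertions = list(
                   list(type = "order", pats = c("search(box(f,X))", "search(obj(s1,X))",
                                                 "grasp(obj(toy,X))")))),
    obs64 = list(circuit = "obs64", config = list(mode = "strong", coincidence_window = 8L),
                 scenario = function(p) make_scenario("obs64", p),
                 max_cycles = 48L,
                 assertions = list(
                   list(type = "order", pats = c("open(box(f,X))", "search(obj(s1,X))",
                                                 "grasp(obj(toy,X))"))))
  )
}

#' List registered experiments
#'
#' @return character vector of experiment names.
#' @export
list_experiments <- function() names(experiment_registry())

#' Run a simulated experiment
#'
#' Compiles the experiment's circuit, replays its scenario script against
#' the synthetic world (stimuli are sensed at their scripted cycles, world
#' mutations applied covertly, and effector actions fed back as stimuli one
#' cycle later), then evaluates the experiment's behavioral assertions.
#' Everything is deterministic.
#'
#' @param name a registered experiment name (see [list_experiments()]).
#' @param config named list overriding the experiment's run configuration
#'   (e.g. `mode = "strong"`).
#' @param params scenario parameters forwarded to [make_scenario()].
#' @return an object of class `vcog_outcome`: list with the final `model`,
#'   `actions` and `trace` data frames, the `world`, and an `assertions`
#'   data frame (one row per assertion, with `pass`).
#' @export
run_experiment <- function(name, config = list(), params = list()) {
  reg <- experiment_registry()
  exp <- reg[[name]]
  if (is.null(exp)) stop(sprintf("unknown experiment '%s'", name))
  cfg <- exp$config
  cfg[names(config)] <- config
  sc <- exp$scenario(params)
  spec <- build_circuit(exp$circuit)
  m <- compile_circuit(spec, new_model(cfg))
  wd <- sc$world
  w <- new_world(objects = wd$objects %||% list(), screens = wd$screens %||% list(),
                 boxes = wd$boxes %||% list(),
                 feedback = wd$feedback %||% character(0))
  out <- run_scenario(m, w, sc, max_cycles = exp$max_cycles)
  acts <- get_actions(m)
  checks <- eval_assertions(exp$assertions, acts)
  structure(list(name = name, model = m, world = w, actions = acts,
                 trace = get_trace(m), assertions = checks,
                 phases = out$phases),
            class = "vcog_outcome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay a scenario against a compiled model and world
#'
#' The driver loop behind [run_experiment()], exposed so that custom
#' circuit/script pairs can be exercised: each cycle applies the scripted
#' world mutations, senses the scripted and fed-back stimuli, reacts, and
#' converts the cycle's actions into next-cycle stimuli via [world_step()].
#'
#' @param m compiled model.
#' @param w world.
#' @param sc scenario.
#' @param max_cycles cycle bound.
#' @return list with `phases` (phase label -> entry cycle).
#' @export
run_scenario <- function(m, w, sc, max_cycles = 60L) {
  by_cycle <- split(sc$events, vapply(sc$events, function(e) e$cycle, 0L))
  last_scripted <- max(vapply(sc$events, function(e) e$cycle, 0L))
  phases <- list()
  repeat {
    t <- m$cycle
    if (t > max_cycles) { m$truncated <- TRUE; trace_event(m, "warn", "cycle limit reached"); break }
    evs <- by_cycle[[as.character(t)]] %||% list()
    for (e in evs) {
      if (e$kind == "phase") { phases[[e$value]] <- t; trace_event(m, "phase", e$value) }
      if (e$kind == "mutate") world_mutate(w, e$value)
    }
    batch <- c(lapply(Filter(function(e) e$kind == "stim", evs), function(e) vt(e$value)),
               m$pending[[as.character(t)]])
    m$pending[[as.character(t)]] <- NULL
    n_before <- length(m$actions)
    for (input in batch) sense(m, input)
    applied <- react(m)
    acts <- if (length(m$actions) > n_before)
      lapply(m$actions[(n_before + 1L):length(m$actions)], function(a) a$term) else list()
    for (stim in world_step(w, t, acts)) schedule_stimulus(m, t + 1L, stim)
    pending_left <- length(m$pending) > 0L && any(vapply(m$pending, length, 0L) > 0L)
    quiescent <- applied == 0L && length(m$queue) == 0L && !pending_left
    end_cycle(m)
    if (t >= last_scripted && quiescent) break
  }
  list(phases = phases)
}

# Behavioral assertions over the emitted action sequence. Patterns are
# terms (named variables match anything); types:
#   present - some action matches `pat` (optionally only after cycle `after`)
#   absent  - no action matches `pat`
#   before  - no action up to cycle `upto` matches `absent`
#   order   - `pats` match a subsequence of the actions, in order
eval_assertions <- function(assertions, actions) {
  terms <- lapply(actions$action, vt)
  cycles <- actions$cycle
  match1 <- function(pat, from = 1L, lo_cycle = -Inf, hi_cycle = Inf) {
    if (from > length(terms)) return(0L)
    for (k in from:length(terms)) {
      if (cycles[[k]] < lo_cycle || cycles[[k]] > hi_cycle) next
      if (!is.null(unify(freshen(vt(pat)), terms[[k]]))) return(k)
    }
    0L
  }
  rows <- lapply(assertions, function(a) {
    pass <- switch(a$type,
      present = match1(a$pat, lo_cycle = a$after %||% -Inf) > 0L,
      absent = match1(a$pat) == 0L,
      before = match1(a$absent, hi_cycle = a$upto) == 0L,
      order = {
        k <- 0L; ok <- TRUE
        for (pat in a$pats) {
          k <- match1(pat, from = k + 1L)
          if (k == 0L) { ok <- FALSE; break }
        }
        ok
      },
      stop(sprintf("unknown assertion type '%s'", a$type))
    )
    desc <- switch(a$type,
      present = sprintf("action %s emitted", a$pat),
      absent = sprintf("no action %s", a$pat),
      before = sprintf("no action %s up to cycle %d", a$absent, a$upto),
      order = sprintf("ordered: %s", paste(a$pats, collapse = " .. ")))
    data.frame(assertion = desc, pass = pass, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.vcog_outcome <- function(x, ...) {
  cat(sprintf("experiment '%s': %d actions, %d trace events\n",
              x$name, nrow(x$actions), nrow(x$trace)))
  for (k in seq_len(nrow(x$actions)))
    cat(sprintf("  cycle %2d  %s\n", x$actions$cycle[[k]], x$actions$action[[k]]))
  for (k in seq_len(nrow(x$assertions)))
    cat(sprintf("  [%s] %s\n", if (x$assertions$pass[[k]]) "ok" else "FAIL",
                x$assertions$assertion[[k]]))
  invisible(x)
}

## ---- golden traces ---------------------------------------------------------

#' Write golden traces
#'
#' Regenerates every experiment under its default configuration and writes
#' the canonical traces (one `.trc` text file per experiment) to `dir`.
#'
#' @param dir output directory (created if needed).
#' @param experiments experiment names (default: all).
#' @return invisible vector of written paths.
#' @export
write_goldens <- function(dir, experiments = list_experiments()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(experiments, function(nm) {
    out <- run_experiment(nm)
    path <- file.path(dir, paste0(nm, ".trc"))
    writeLines(format_trace(out$model), path)
    path
  }, "")
  invisible(paths)
}

#' Compare experiments against golden traces
#'
#' Re-runs every experiment with a golden trace in `dir` and compares
#' canonical traces; missing goldens are listed, not fatal, and unknown
#' files produce a warning entry.
#'
#' @param dir directory of `.trc` files from [write_goldens()].
#' @param experiments experiment names (default: all).
#' @return data.frame with columns experiment, status
#'   (`equal`/`diff`/`missing`), detail.
#' @export
regress <- function(dir, experiments = list_experiments()) {
  known <- paste0(experiments, ".trc")
  extra <- setdiff(list.files(dir, pattern = "\\.trc$"), known)
  rows <- list()
  for (f in extra)
    rows[[length(rows) + 1L]] <- data.frame(experiment = sub("\\.trc$", "", f),
                                            status = "unknown", detail = "no such experiment",
                                            stringsAsFactors = FALSE)
  for (nm in experiments) {
    path <- file.path(dir, paste0(nm, ".trc"))
    if (!file.exists(path)) {
      rows[[length(rows) + 1L]] <- data.frame(experiment = nm, status = "missing",
                                              detail = path, stringsAsFactors = FALSE)
      next
    }
    golden <- readLines(path)
    fresh <- format_trace(run_experiment(nm)$model)
    if (identical(golden, fresh)) {
      rows[[length(rows) + 1L]] <- data.frame(experiment = nm, status = "equal",
                                              detail = "", stringsAsFactors = FALSE)
    } else {
      idx <- which(golden != c(fresh, rep("", max(0, length(golden) - length(fresh)))))[1]
      if (is.na(idx)) idx <- min(length(golden), length(fresh)) + 1L
      rows[[length(rows) + 1L]] <- data.frame(experiment = nm, status = "diff",
                                              detail = sprintf("first divergence at event %d", idx),
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
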