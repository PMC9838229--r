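# Synthetic one-dimensional world and scenario scripting.
#
# The world holds movable objects, occluding screens and covered boxes on an
# integer axis, applies scripted mutations (including the experimenter's
# covert manipulations, which deliberately emit NO stimuli - that is what
# makes a displacement invisible to the subject), and converts effector
# actions back into stimuli with a latency of exactly one cycle, closing the
# perception-action loop.

#' Create a world state
#'
#' @param objects named list `name -> position` of movable objects.
#' @param screens named list `name -> position` of occluding screens.
#' @param boxes named list `name -> position` of boxes.
#' @param feedback character vector of enabled action->stimulus rules,
#'   a subset of `c("search", "open", "grasp", "reward")`; `reward` makes a
#'   successful grasp emit an `excite` reinforcement.
#' @return an environment of class `vcog_world`.
#' @export
new_world <- function(objects = list(), screens = list(), boxes = list(),
                      feedback = c("search", "open", "grasp")) {
  w <- new.env(parent = emptyenv())
  w$objects <- lapply(objects, function(p) list(pos = as.integer(p), where = "axis", at = NA_character_))
  w$screens <- lapply(screens, as.integer)
  w$boxes <- lapply(boxes, function(p) list(pos = as.integer(p), covered = FALSE))
  w$feedback <- feedback
  w$log <- character(0)
  class(w) <- c("vcog_world", class(w))
  w
}

world_log <- function(w, msg) { w$log <- c(w$log, msg); invisible(w) }

#' Apply a world mutation
#'
#' Mutations are ground terms: `place(o,X)` puts object `o` on the axis at
#' `X`; `hide(o,S)` puts it under screen `S`; `boxput(o,F)` into box `F`;
#' `boxmove(F,X)` moves a box (contents travel with it); `boxcover(F)` /
#' `boxuncover(F)` toggle the lid; `boxempty(F,S)` covertly transfers the
#' box's contents under screen `S`; `remove(o)` takes an object out of the
#' world. Mutations never emit stimuli.
#'
#' @param w world.
#' @param mut a mutation term (or literal string).
#' @return the world, invisibly.
#' @export
world_mutate <- function(w, mut) {
  if (is.character(mut)) mut <- vt(mut)
  stopifnot(mut$k == "c")
  a <- function(i) mut$args[[i]]$v
  switch(mut$f,
    place = { w$objects[[a(1)]] <- list(pos = as.integer(a(2)), where = "axis", at = NA_character_) },
    hide = {
      o <- w$objects[[a(1)]]; s <- a(2)
      o$where <- "screen"; o$at <- s; o$pos <- w$screens[[s]]
      w$objects[[a(1)]] <- o
    },
    boxput = {
      o <- w$objects[[a(1)]]
      o$where <- "box"; o$at <- a(2); o$pos <- w$boxes[[a(2)]]$pos
      w$objects[[a(1)]] <- o
    },
    boxmove = {
      f <- a(1); w$boxes[[f]]$pos <- as.integer(a(2))
      for (nm in names(w$objects)) {
        if (identical(w$objects[[nm]]$where, "box") && identical(w$objects[[nm]]$at, f))
          w$objects[[nm]]$pos <- as.integer(a(2))
      }
    },
    boxcover = { w$boxes[[a(1)]]$covered <- TRUE },
    boxuncover = { w$boxes[[a(1)]]$covered <- FALSE },
    boxempty = {
      f <- a(1); s <- a(2)
      for (nm in names(w$objects)) {
        o <- w$objects[[nm]]
        if (identical(o$where, "box") && identical(o$at, f)) {
          o$where <- "screen"; o$at <- s; o$pos <- w$screens[[s]]
          w$objects[[nm]] <- o
        }
      }
    },
    remove = { w$objects[[a(1)]]$where <- "gone" },
    stop(sprintf("unknown mutation '%s'", mut$f))
  )
  invisible(w)
}

under_screen <- function(w, s) {
  for (nm in names(w$objects)) {
    o <- w$objects[[nm]]
    if (identical(o$where, "screen") && identical(o$at, s)) return(nm)
  }
  NULL
}

in_box <- function(w, f) {
  for (nm in names(w$objects)) {
    o <- w$objects[[nm]]
    if (identical(o$where, "box") && identical(o$at, f)) return(nm)
  }
  NULL
}

#' Convert effector actions into consequent stimuli
#'
#' Applies the enabled feedback rules to the actions emitted at `cycle`:
#' a search at a screen hiding an object uncovers it (a `view` stimulus at
#' the next cycle); a search at an empty screen or in an empty box yields a
#' `spot(...empty...)` failure; opening a box reports its content or its
#' emptiness; a grasp removes the object from the world (and under the
#' `reward` rule emits `excite`). Actions referencing nonexistent entities
#' are logged no-ops. Feedback latency is exactly one cycle.
#'
#' @param w world.
#' @param cycle the cycle the actions were emitted at.
#' @param actions list of ground action terms.
#' @return list of stimulus terms to schedule at `cycle + 1`.
#' @export
world_step <- function(w, cycle, actions) {
  out <- list()
  emit <- function(t) out[[length(out) + 1L]] <<- t
  for (act in actions) {
    if (is.character(act)) act <- vt(act)
    if (act$k != "c") next
    arg1 <- act$args[[1]]
    switch(act$f,
      search = {
        if (!"search" %in% w$feedback) next
        if (arg1$k == "c" && arg1$f == "obj") {
          s <- arg1$args[[1]]$v; x <- arg1$args[[2]]$v
          if (is.null(w$screens[[s]])) { world_log(w, sprintf("search at unknown screen %s", s)); next }
          o <- under_screen(w, s)
          if (is.null(o)) emit(vt(sprintf("spot(obj(%s,empty,%d))", s, x)))
          else {
            w$objects[[o]]$where <- "axis"
            emit(vt(sprintf("view(obj(%s,%d))", o, x)))
          }
        } else if (arg1$k == "c" && arg1$f == "box") {
          f <- arg1$args[[1]]$v; x <- arg1$args[[2]]$v
          if (is.null(w$boxes[[f]])) { world_log(w, sprintf("search in unknown box %s", f)); next }
          o <- in_box(w, f)
          if (is.null(o)) emit(vt(sprintf("spot(box(%s,empty,%d))", f, x)))
          else {
            w$objects[[o]]$where <- "axis"
            emit(vt(sprintf("view(obj(%s,%d))", o, x)))
          }
        }
      },
      open = {
        if (!"open" %in% w$feedback) next
        f <- arg1$args[[1]]$v; x <- arg1$args[[2]]$v
        if (is.null(w$boxes[[f]])) { world_log(w, sprintf("open of unknown box %s", f)); next }
        w$boxes[[f]]$covered <- FALSE
        o <- in_box(w, f)
        if (is.null(o)) emit(vt(sprintf("spot(box(%s,empty,%d))", f, x)))
        else emit(vt(sprintf("spot(box(%s,%s,%d))", f, o, x)))
      },
      grasp = {
        if (!"grasp" %in% w$feedback) next
        p <- arg1$args[[1]]$v
        if (is.null(w$objects[[p]]) || identical(w$objects[[p]]$where, "gone")) {
          world_log(w, sprintf("grasp of absent object %s", p)); next
        }
        w$objects[[p]]$where <- "gone"
        if ("reward" %in% w$feedback) emit(vt("excite"))
      },
      { NULL }  # look and other actions have no world consequence
    )
  }
  out
}

## ---- scenario scripts ------------------------------------------------------

scenario_new <- function(name, world, events) {
  structure(list(name = name, world = world, events = events), class = "vcog_scenario")
}

ev_stim <- function(cycle, term) list(cycle = as.integer(cycle), kind = "stim", value = term)
ev_mut <- function(cycle, term) list(cycle = as.integer(cycle), kind = "mutate", value = term)
ev_phase <- function(cycle, label) list(cycle = as.integer(cycle), kind = "phase", value = label)

# One tracked box trial: the box (with the toy inside unless `empty_at`
# manipulations intervene) is carried along the axis, passes under screens,
# and stops. Returns events relative to `t0`.
box_trial <- function(t0, screens_passed, covered, phase) {
  ev <- list(ev_phase(t0 + 1L, phase))
  add <- function(e) ev[[length(ev) + 1L]] <<- e
  if (covered) {
    add(ev_stim(t0 + 1L, "open(box(f,toy,1))"))
    add(ev_stim(t0 + 2L, "close(box(f,lid,1))"))
  } else {
    add(ev_stim(t0 + 1L, "view(box(f,toy,1))"))
  }
  add(ev_mut(t0 + 1L, "place(toy,1)"))
  add(ev_mut(t0 + 1L, "boxput(toy,f)"))
  add(ev_mut(t0 + 1L, "boxmove(f,1)"))
  t <- t0 + 2L
  pos <- 1L
  for (s in names(screens_passed)) {
    spos <- screens_passed[[s]]
    add(ev_stim(t + 1L, sprintf("move(obj(f,%d))", spos - 1L)))
    add(ev_mut(t + 1L, sprintf("boxmove(f,%d)", spos - 1L)))
    add(ev_stim(t + 2L, sprintf("see(obj(%s,%d))", s, spos)))
    add(ev_mut(t + 2L, sprintf("boxmove(f,%d)", spos)))
    t <- t + 2L
    pos <- spos
  }
  list(events = ev, t = t, pos = pos)
}

#' Build a named scenario script
#'
#' Deterministic constructors for the stimulus schedules of the simulated
#' experiments; identical parameters always yield identical scripts.
#' Available names: `aplysia` (classical conditioning; `pairings`, `paired`),
#' `operant` (`reinforce` = `"excite"`/`"inhibit"`, `input`), `grasp`
#' (`match` = `"same"`/`"position"`/`"cycle"`), `track` (`variant` =
#' `"stops_in_view"`/`"occluded"`), `anotb`, `obs55` (`reps` phase-I
#' repetitions before phase II), `obs64`.
#'
#' @param name scenario name.
#' @param params named list of scenario parameters.
#' @return a `vcog_scenario`: world description plus timed events.
#' @export
make_scenario <- function(name, params = list()) {
  p <- function(key, default) if (is.null(params[[key]])) default else params[[key]]
  switch(name,
    aplysia = {
      pairings <- p("pairings", 2L)
      paired <- p("paired", TRUE)
      gap <- if (paired) 1L else 3L   # us lag; outside the window when unpaired
      ev <- list(ev_stim(1L, "cs"))   # pre-training probe
      t <- 3L
      for (i in seq_len(pairings)) {
        ev <- c(ev, list(ev_stim(t, "cs"), ev_stim(t + gap, "us")))
        t <- t + gap + 2L
      }
      ev <- c(ev, list(ev_stim(t + 1L, "cs")))  # post-training probe
      scenario_new("aplysia", list(feedback = character(0)), ev)
    },
    operant = {
      rf <- p("reinforce", "excite")
      input <- p("input", "cue")
      ev <- list(
        ev_stim(1L, sprintf("watch(%s)", input)),
        ev_stim(2L, if (rf == "excite") "excite" else "inhibit"),
        ev_stim(4L, sprintf("watch(%s)", input))
      )
      scenario_new("operant", list(feedback = character(0)), ev)
    },
    grasp = {
      match <- p("match", "same")
      ev <- switch(match,
        same = list(ev_stim(1L, "view(obj(toy,3))"), ev_stim(1L, "view(hand(3))")),
        position = list(ev_stim(1L, "view(obj(toy,3))"), ev_stim(1L, "view(hand(4))")),
        cycle = list(ev_stim(1L, "view(obj(toy,3))"), ev_stim(2L, "view(hand(3))")),
        stop(sprintf("unknown grasp variant '%s'", match))
      )
      scenario_new("grasp", list(feedback = character(0)), ev)
    },
    track = {
      variant <- p("variant", "stops_in_view")
      ev <- list(
        ev_stim(1L, "move(obj(toy,1))"),
        ev_stim(2L, "move(obj(toy,2))")
      )
      if (variant == "stops_in_view") {
        ev <- c(ev, list(ev_stim(3L, "see(obj(toy,3))"), ev_stim(4L, "halt(obj(toy,3))")))
      } else if (variant == "occluded") {
        ev <- c(ev, list(ev_stim(3L, "see(obj(s1,3))")))
      } else stop(sprintf("unknown track variant '%s'", variant))
      scenario_new("track", list(objects = list(toy = 1), screens = list(s1 = 3),
                                 feedback = "search"), ev)
    },
    anotb = {
      screens <- p("screens", list(s1 = 3L, s2 = 5L))
      sn <- names(screens)
      ev <- list(
        ev_phase(1L, "first_hiding"),
        ev_stim(1L, "move(obj(toy,1))"),
        ev_stim(2L, "move(obj(toy,2))"),
        ev_stim(3L, sprintf("see(obj(%s,%d))", sn[[1]], screens[[1]])),
        ev_mut(3L, sprintf("hide(toy,%s)", sn[[1]])),
        ev_stim(4L, sprintf("halt(obj(%s,%d))", sn[[1]], screens[[1]])),
        ev_phase(6L, "second_hiding"),
        ev_mut(6L, sprintf("place(toy,%d)", screens[[2]] - 1L)),
        ev_stim(6L, sprintf("move(obj(toy,%d))", screens[[2]] - 1L)),
        ev_stim(7L, sprintf("see(obj(%s,%d))", sn[[2]], screens[[2]])),
        ev_mut(7L, sprintf("hide(toy,%s)", sn[[2]])),
        ev_stim(8L, sprintf("halt(obj(%s,%d))", sn[[2]], screens[[2]]))
      )
      scenario_new("anotb", list(objects = list(toy = 1), screens = screens,
                                 feedback = c("search", "grasp")), ev)
    },
    obs55 = {
      reps <- p("reps", 2L)
      phase3_only <- isTRUE(p("phase3_only", FALSE))  # naive subject, no apprenticeship
      box_phase <- function(t0, phase) {
        tr <- box_trial(t0, c(s1 = 3L), covered = FALSE, phase = phase)
        t <- tr$t
        c(tr$events, list(
          ev_mut(t0 + 4L, "boxempty(f,s1)"),   # covert
          ev_stim(t + 1L, "move(obj(f,4))"), ev_mut(t + 1L, "boxmove(f,4)"),
          ev_stim(t + 2L, "see(obj(f,5))"),
          ev_stim(t + 3L, "halt(box(f,5))"),
          ev_stim(t + 3L, "stop(box(f,5))"), ev_mut(t + 3L, "boxmove(f,5)")
        ))
      }
      if (phase3_only) {
        ev <- box_phase(0L, "III")
      } else {
        ev <- list()
        for (i in seq_len(reps)) ev <- c(ev, box_phase((i - 1L) * 12L, sprintf("I.%d", i)))
        # phase II: the box is left under the screen with the object inside
        u <- reps * 12L
        ev <- c(ev, list(
          ev_phase(u + 1L, "II"),
          ev_stim(u + 1L, "view(box(f,toy,1))"),
          ev_mut(u + 1L, "place(toy,1)"), ev_mut(u + 1L, "boxput(toy,f)"),
          ev_mut(u + 1L, "boxmove(f,1)"),
          ev_stim(u + 2L, "move(obj(f,2))"), ev_mut(u + 2L, "boxmove(f,2)"),
          ev_stim(u + 3L, "see(obj(s1,3))"), ev_mut(u + 3L, "boxmove(f,3)"),
          ev_stim(u + 4L, "stop(box(f,3))"), ev_mut(u + 4L, "boxempty(f,s1)"),
          ev_stim(u + 5L, "halt(obj(s1,3))")
        ))
        ev <- c(ev, box_phase(u + 12L, "III"))
      }
      ev <- ev[order(vapply(ev, function(e) e$cycle, 0L), method = "radix")]
      scenario_new("obs55", list(objects = list(toy = 1), screens = list(s1 = 3),
                                 boxes = list(f = 1),
                                 feedback = c("search", "open", "grasp", "reward")), ev)
    },
    obs64 = {
      ev <- list()
      # phase Ia: one screen, box opened (empty), then screen searched
      tr <- box_trial(0L, c(s1 = 3L), covered = TRUE, phase = "Ia")
      ev <- c(ev, tr$events, list(ev_mut(4L, "boxempty(f,s1)")))
      ev <- c(ev, list(
        ev_stim(tr$t + 1L, "move(obj(f,4))"), ev_mut(tr$t + 1L, "boxmove(f,4)"),
        ev_stim(tr$t + 2L, "see(obj(f,5))"),
        ev_stim(tr$t + 3L, "stop(box(f,5))"), ev_mut(tr$t + 3L, "boxmove(f,5)")
      ))
      # phase Ib: a different screen; the box is not reopened (LTB) and the
      # second screen is searched immediately
      b <- 12L
      tr <- box_trial(b, c(s2 = 5L), covered = TRUE, phase = "Ib")
      ev <- c(ev, tr$events, list(ev_mut(b + 4L, "boxempty(f,s2)")))
      ev <- c(ev, list(
        ev_stim(tr$t + 1L, "move(obj(f,6))"), ev_mut(tr$t + 1L, "boxmove(f,6)"),
        ev_stim(tr$t + 2L, "see(obj(f,7))"),
        ev_stim(tr$t + 3L, "stop(box(f,7))"), ev_mut(tr$t + 3L, "boxmove(f,7)")
      ))
      # phase II: two successive screens; FIFO order of remembered looks
      c0 <- 24L
      tr <- box_trial(c0, c(s1 = 3L, s2 = 5L), covered = TRUE, phase = "II")
      ev <- c(ev, tr$events, list(ev_mut(c0 + 6L, "boxempty(f,s2)")))
      ev <- c(ev, list(
        ev_stim(tr$t + 1L, "move(obj(f,6))"), ev_mut(tr$t + 1L, "boxmove(f,6)"),
        ev_stim(tr$t + 2L, "see(obj(f,7))"),
        ev_stim(tr$t + 3L, "stop(box(f,7))"), ev_mut(tr$t + 3L, "boxmove(f,7)")
      ))
      ev <- ev[order(vapply(ev, function(e) e$cycle, 0L), method = "radix")]
      scenario_new("obs64", list(objects = list(toy = 1), screens = list(s1 = 3, s2 = 5),
                                 boxes = list(f = 1),
                                 feedback = c("search", "open", "grasp")), ev)
    },
    stop(sprintf("unknown scenario '%s'", name))
  )
}

#' Save / load a scenario script
#'
#' Scenario scripts round-trip through YAML: world description (objects,
#' screens, boxes, feedback rules) and the ordered timed events. Loading
#' validates the schema and that event cycles are non-decreasing.
#'
#' @param sc a `vcog_scenario`.
#' @param path file path.
#' @return `load_scenario`: a `vcog_scenario`; `save_scenario`: the path,
#'   invisibly.
#' @export
save_scenario <- function(sc, path) {
  doc <- list(name = sc$name, world = sc$world,
              events = lapply(sc$events, function(e)
                list(cycle = e$cycle, kind = e$kind, value = e$value)))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname save_scenario
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such scenario file: %s", path))
  doc <- yaml::read_yaml(path)
  if (is.null(doc$name) || is.null(doc$events) || length(doc$events) == 0L)
    stop("scenario schema violation: need 'name' and non-empty 'events'")
  cycles <- vapply(doc$events, function(e) as.integer(e$cycle), 0L)
  if (any(diff(cycles) < 0L))
    stop(sprintf("scenario schema violation: decreasing cycle at event %d",
                 which(diff(cycles) < 0L)[[1]] + 1L))
  for (k in seq_along(doc$events)) {
    e <- doc$events[[k]]
    if (!e$kind %in% c("stim", "mutate", "phase"))
      stop(sprintf("scenario schema violation: unknown kind '%s' at event %d", e$kind, k))
    if (e$kind %in% c("stim", "mutate")) vt(e$value)  # must parse
    doc$events[[k]]$cycle <- as.integer(e$cycle)
  }
  w <- doc$world
  scenario_new(doc$name,
               list(objects = w$objects, screens = w$screens, boxes = w$boxes,
                    feedback = unlist(w$feedback)),
               doc$events)
}
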