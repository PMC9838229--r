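# Plasticity protocols: STP expiry, weak vs strong LTP, LTD, the
# associative store (LTS/LTR), LTB and the FIFO short-term memory.

test_that("short-term potentiation opens a pathway and expires on schedule", {
  m <- toy_model(w = 0L)
  vm_fire(m, "p", term = vt("p(1)"))
  vm_send(m, "p", "q", vt("q(1)"))
  stp_open(m, "s", "p", "q", 1L)
  expect_length(vm_deliver(m, "q"), 1L)          # open this cycle
  virtcog:::end_cycle(m)
  virtcog:::end_cycle(m)
  vm_fire(m, "p", term = vt("p(2)"))
  vm_send(m, "p", "q", vt("q(2)"))
  expect_length(vm_deliver(m, "q"), 0L)          # closed again at cycle +2
})

aplysia_model <- function(mode = "weak") {
  compile_circuit(build_circuit("aplysia"), new_model(list(mode = mode)))
}

test_that("paired stimuli within the window potentiate; unpaired never do", {
  m <- aplysia_model()
  run_vm(m, list(list(cycle = 1, term = "cs"), list(cycle = 2, term = "us"),
                 list(cycle = 4, term = "cs"), list(cycle = 5, term = "us"),
                 list(cycle = 8, term = "cs")), max_cycles = 12)
  expect_gte(get_weight(m, "s", "s_cs", "motor"), 1L)
  probe <- get_actions(m)
  expect_true("motor(cs)" %in% probe$action[probe$cycle == 8])

  m2 <- aplysia_model()
  run_vm(m2, list(list(cycle = 1, term = "cs"), list(cycle = 4, term = "us"),
                  list(cycle = 7, term = "cs")), max_cycles = 10)
  expect_equal(get_weight(m2, "s", "s_cs", "motor"), 0L)
  expect_false("motor(cs)" %in% get_actions(m2)$action)
})

test_that("potentiation occurs iff a pairing lies within the window (schedule scan)", {
  set.seed(11)
  window <- 1L
  for (rep in 1:30) {
    cs_t <- sort(sample.int(9L, sample.int(2L, 1L)))
    us_t <- sort(sample.int(9L, sample.int(2L, 1L)))
    m <- aplysia_model()
    stim <- c(lapply(cs_t, function(t) list(cycle = t, term = "cs")),
              lapply(us_t, function(t) list(cycle = t, term = "us")))
    run_vm(m, stim, max_cycles = 12)
    coincident <- any(outer(cs_t, us_t, function(a, b) abs(a - b) <= window))
    expect_identical(get_weight(m, "s", "s_cs", "motor") > 0L, coincident,
                     label = sprintf("cs=%s us=%s", paste(cs_t, collapse = ","),
                                     paste(us_t, collapse = ",")))
  }
})

# a minimal potentiable circuit with two distinct instantiations
two_instance_circuit <- function() {
  parse_circuit("
circuit two
stream s
node sensor s trig go(X)
node sensor s cue cue(X)
node effector s act act(X)
edge synapse trig act w=0 plasticity=ltp:cue
")
}

test_that("weak plasticity binds the first instance; strong rebinds", {
  stim <- list(list(cycle = 1, term = "go(2)"), list(cycle = 1, term = "cue(2)"),
               list(cycle = 4, term = "go(7)"), list(cycle = 4, term = "cue(7)"))
  weak <- compile_circuit(two_instance_circuit(), new_model(list(mode = "weak")))
  run_vm(weak, stim, max_cycles = 8)
  strong <- compile_circuit(two_instance_circuit(), new_model(list(mode = "strong")))
  run_vm(strong, stim, max_cycles = 8)
  aw <- get_actions(weak)$action
  as_ <- get_actions(strong)$action
  expect_identical(aw, c("act(2)", "act(2)"))   # perseveration on the first binding
  expect_identical(as_, c("act(2)", "act(7)"))  # successive associations
})

test_that("weak and strong runs coincide when only one instantiation occurs", {
  stim <- list(list(cycle = 1, term = "go(2)"), list(cycle = 1, term = "cue(2)"),
               list(cycle = 4, term = "go(2)"), list(cycle = 4, term = "cue(2)"))
  weak <- compile_circuit(two_instance_circuit(), new_model(list(mode = "weak")))
  run_vm(weak, stim, max_cycles = 8)
  strong <- compile_circuit(two_instance_circuit(), new_model(list(mode = "strong")))
  run_vm(strong, stim, max_cycles = 8)
  expect_identical(get_actions(weak), get_actions(strong))
})

test_that("pathway weights are non-decreasing absent LTD and LTB", {
  m <- aplysia_model()
  run_vm(m, list(list(cycle = 1, term = "cs"), list(cycle = 2, term = "us"),
                 list(cycle = 4, term = "cs"), list(cycle = 5, term = "us")),
         max_cycles = 8)
  tr <- get_trace(m)
  ws <- tr$text[tr$kind == "weight"]
  vals <- as.integer(sub(".*= (\\d+).*", "\\1", ws[grepl("s_cs->motor", ws)]))
  expect_true(all(diff(vals) >= 0L))
})

test_that("the associative store retrieves newest-first with exact bindings", {
  m <- new_model()
  add_template(m, "watch", "internal", "s", vt("watch(F)"))
  add_template(m, "act", "internal", "s", vt("act(F,I,X)"))
  weight_init(m, "s", "watch", "act", 0L)

  expect_error(lts(m, vt("image(box(f,P,3))")), "ground")
  expect_null(ltr(m, vt("image(box(F,I,X))"), "watch", "act"))  # empty store, no cue

  lts(m, vt("image(box(f,toy,3))"))
  vm_fire(m, "watch", term = vt("watch(f)"))
  s <- ltr(m, vt("image(box(F,I,X))"), "watch", "act")
  expect_equal(format_term(s$I), "toy")
  expect_equal(format_term(s$X), "3")
  expect_equal(get_weight(m, "s", "watch", "act"), 1L)
  # the retrieval bindings reproduce the stored trace exactly
  expect_identical(format_term(subst_apply(s, vt("image(box(F,I,X))"))),
                   "image(box(f,toy,3))")
  tr <- get_trace(m)
  expect_true(any(tr$text == "act act(f,toy,3)"))

  lts(m, vt("image(box(f,ball,5))"))
  s2 <- ltr(m, vt("image(box(f,I,X))"), "watch", "act")
  expect_equal(format_term(s2$I), "ball")  # newest trace wins

  ltb(m, "s", "watch", "act")
  expect_null(ltr(m, vt("image(box(f,I,X))"), "watch", "act"))  # blocked edge suppresses recall
})

test_that("short-term memory is FIFO, ground-only, and empty-safe", {
  m <- new_model()
  expect_null(stm_pop(m, "looks"))
  expect_error(stm_push(m, "looks", vt("look(obj(Q,2))")), "ground")
  stm_push(m, "looks", vt("look(obj(s1,2))"))
  stm_push(m, "looks", vt("look(obj(s2,4))"))
  expect_equal(format_term(stm_pop(m, "looks")), "look(obj(s1,2))")
  expect_equal(format_term(stm_pop(m, "looks")), "look(obj(s2,4))")
  expect_null(stm_pop(m, "looks"))
})
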