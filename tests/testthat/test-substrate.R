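# Substrate: firing, weight-gated asynchronous delivery, join/merge
# coincidence, and the weight-table invariants.

test_that("firing activates an instance once per cycle and logs it", {
  m <- toy_model()
  id1 <- vm_fire(m, "p", term = vt("p(1)"))
  id2 <- vm_fire(m, "p", term = vt("p(1)"))  # idempotent within the cycle
  expect_false(is.na(id1))
  expect_true(is.na(id2))
  expect_equal(sum(get_trace(m)$kind == "fire"), 1L)
  vm_fire(m, "p", binding = list(X = vt_atom("cs")))
  tr <- get_trace(m)
  expect_true(any(tr$text == "p p(cs)"))
  expect_error(vm_fire(m, "nosuch"), "unknown template")
})

test_that("delivery is gated by the threshold and consumes matching signals", {
  m <- toy_model(w = 0L)
  vm_fire(m, "p", term = vt("p(1)"))
  expect_true(vm_send(m, "p", "q", vt("q(1)")))
  expect_length(vm_deliver(m, "q"), 0L)   # weight 0 < theta
  expect_length(m$queue, 1L)              # sub-threshold signals stay queued
  adjust_weight(m, "s", "p", "q", +1L)
  expect_length(vm_deliver(m, "q"), 1L)
  expect_length(m$queue, 0L)
  expect_true(any(get_trace(m)$kind == "deliver"))
})

test_that("sends from dormant templates are protocol errors, not exceptions", {
  m <- toy_model()
  expect_false(vm_send(m, "p", "q", vt("q(1)")))
  expect_true(any(grepl("dormant", get_trace(m)$text)))
})

test_that("signals preserve FIFO order per sender-receiver pair", {
  m <- toy_model(w = 1L)
  vm_fire(m, "p", term = vt("p(0)"))
  for (k in 1:4) vm_send(m, "p", "q", vt(sprintf("q(%d)", k)))
  got <- vapply(vm_deliver(m, "q"), format_term, "")
  expect_identical(got, sprintf("q(%d)", 1:4))
})

test_that("no delivery ever crosses streams", {
  m <- toy_model(w = 1L, stream_q = "other")
  vm_fire(m, "p", term = vt("p(1)"))
  vm_send(m, "p", "q", vt("q(1)"))
  expect_length(vm_deliver(m, "q"), 0L)
  expect_true(any(grepl("cross-stream", get_trace(m)$text)))
})

test_that("weight adjustment floors at zero and BLOCKED is absorbing", {
  m <- toy_model(w = 0L)
  adjust_weight(m, "s", "p", "q", +1L)
  expect_equal(get_weight(m, "s", "p", "q"), 1L)
  adjust_weight(m, "s", "p", "q", -1L)
  adjust_weight(m, "s", "p", "q", -1L)
  expect_equal(get_weight(m, "s", "p", "q"), 0L)  # floor
  ltb(m, "s", "p", "q")
  expect_identical(get_weight(m, "s", "p", "q"), "BLOCKED")
  adjust_weight(m, "s", "p", "q", +5L)
  stp_open(m, "s", "p", "q", 3L)
  expect_identical(get_weight(m, "s", "p", "q"), "BLOCKED")
  vm_fire(m, "p", term = vt("p(1)"))
  vm_send(m, "p", "q", vt("q(1)"))
  expect_length(vm_deliver(m, "q"), 0L)  # blocked edges never deliver
})

test_that("join and merge synchronize only within the coincidence window", {
  m <- toy_model()
  register_protocol <- virtcog:::register_protocol
  register_protocol(m, "pid", "s", "p", "q")

  # merge then join in the same cycle, window 1 -> coincidence
  m$cycle <- 5L
  expect_false(vm_merge(m, "pid", vt("q(1)")))
  expect_true(join_merge(m, "pid", window = 1L))

  # merge at 3, join at 5, window 1 -> no coincidence
  m2 <- toy_model()
  register_protocol(m2, "pid", "s", "p", "q")
  m2$cycle <- 3L
  vm_merge(m2, "pid", vt("q(1)"))
  m2$cycle <- 5L
  expect_false(join_merge(m2, "pid", window = 1L))

  # two joins, one merge: exactly one synchronizes (FIFO priority)
  m3 <- toy_model()
  register_protocol(m3, "pid", "s", "p", "q")
  expect_false(vm_join(m3, "pid"))
  expect_false(vm_join(m3, "pid"))
  expect_true(vm_merge(m3, "pid", vt("q(1)")))
  expect_equal(get_weight(m3, "s", "p", "q"), 2L)          # 1 initial + 1 potentiation
  expect_length(Filter(function(j) !j$used, m3$joins), 1L)  # the other join still waits
})

test_that("weight invariants survive random operation sequences", {
  set.seed(7)
  for (rep in 1:25) {
    m <- toy_model(w = sample(0:1, 1L))
    blocked_seen <- FALSE
    for (step in 1:40) {
      op <- sample(c("adj+", "adj-", "ltb", "stp", "fire", "send", "deliver", "tick"), 1L)
      switch(op,
        "adj+" = adjust_weight(m, "s", "p", "q", +1L),
        "adj-" = adjust_weight(m, "s", "p", "q", -1L),
        "ltb" = { ltb(m, "s", "p", "q"); blocked_seen <- TRUE },
        "stp" = stp_open(m, "s", "p", "q", sample.int(3L, 1L)),
        "fire" = vm_fire(m, "p", term = vt(sprintf("p(%d)", sample.int(5L, 1L)))),
        "send" = vm_send(m, "p", "q", vt(sprintf("q(%d)", sample.int(5L, 1L)))),
        "deliver" = vm_deliver(m, "q"),
        "tick" = virtcog:::end_cycle(m)
      )
      w <- get_weight(m, "s", "p", "q")
      if (identical(w, "BLOCKED")) {
        expect_true(blocked_seen)  # nothing blocks spontaneously
      } else {
        expect_gte(w, 0L)
        expect_false(blocked_seen)  # and nothing unblocks
      }
    }
  }
})

test_that("the weight table dump lists entries with streams", {
  m <- toy_model(w = 2L)
  ltb(m, "s", "q", "p")
  wt <- weight_table(m)
  expect_setequal(wt$weight[wt$sender == "p"], "2")
  expect_setequal(wt$weight[wt$sender == "q"], "BLOCKED")
})
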