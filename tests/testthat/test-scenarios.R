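# The bundled experiments: behavioral assertions, circuit extension chain,
# the weak/strong search contrast, practical-learning monotonicity, the
# LTB and FIFO properties, and golden-trace regression.

test_that("every registered experiment passes its behavioral assertions", {
  for (nm in list_experiments()) {
    out <- run_experiment(nm)
    expect_true(all(out$assertions$pass),
                label = sprintf("assertions of '%s'", nm))
    expect_false(out$model$truncated, label = sprintf("no truncation in '%s'", nm))
  }
})

test_that("each sensory-motor circuit strictly extends the previous one", {
  chain <- c("substage3", "substage4", "substage5", "substage6")
  node_sig <- function(sp) vapply(sp$nodes, function(n)
    paste(n$name, n$kind, n$stream, format_term(n$pattern)), "")
  edge_sig <- function(sp) vapply(sp$edges, function(e)
    paste(e$type, e$from, e$to), "")
  for (k in 2:length(chain)) {
    lo <- build_circuit(chain[[k - 1]])
    hi <- build_circuit(chain[[k]])
    expect_true(all(node_sig(lo) %in% node_sig(hi)),
                label = sprintf("%s nodes in %s", chain[[k - 1]], chain[[k]]))
    expect_true(all(edge_sig(lo) %in% edge_sig(hi)),
                label = sprintf("%s edges in %s", chain[[k - 1]], chain[[k]]))
    expect_gt(length(hi$nodes), length(lo$nodes))
  }
  expect_error(build_circuit("substage9"), "unknown circuit")
})

test_that("weak and strong searching runs differ only at the second search", {
  weak <- run_experiment("anotb", config = list(mode = "weak"))
  strong <- run_experiment("anotb", config = list(mode = "strong"))
  aw <- weak$actions; as_ <- strong$actions

  # identical behavior through the first retrieval and the second look
  expect_identical(aw$action[1:4], as_$action[1:4])
  # the second search is the divergence: first screen (error) vs second
  expect_identical(aw$action[[5]], "search(obj(s1,3))")
  expect_identical(as_$action[[5]], "search(obj(s2,5))")

  # trace prefixes are identical up to the divergence point
  cmp <- compare_traces(weak$model, strong$model)
  expect_false(cmp$equal)
  la <- format_trace(weak$model)
  lb <- format_trace(strong$model)
  expect_identical(la[seq_len(cmp$index - 1L)], lb[seq_len(cmp$index - 1L)])
  # and the divergence happens at the second hiding, not before
  expect_gte(weak$trace$cycle[[cmp$index]], 8L)
})

test_that("practical learning is monotone: phase III needs the apprenticeship", {
  trained <- run_experiment("obs55")
  acts <- trained$actions$action
  expect_true(any(grepl("^search\\(box\\(f", acts)))
  expect_true(any(grepl("^search\\(obj\\(s1", acts)))
  # phase ordering: in phase III the box search precedes the screen search
  ph3 <- trained$phases[["III"]]
  late <- trained$actions[trained$actions$cycle >= ph3, ]
  expect_identical(sub("\\(.*", "", late$action),
                   c("look", "search", "search", "grasp"))
  expect_match(late$action[[2]], "^search\\(box")
  expect_match(late$action[[3]], "^search\\(obj\\(s1")

  # a naive subject running the same protocol never searches the screen
  naive <- run_experiment("obs55", params = list(phase3_only = TRUE))
  expect_false(any(grepl("^search\\(obj\\(", naive$actions$action)))
  expect_true(any(grepl("^search\\(box\\(", naive$actions$action)))
})

test_that("observation 55 phases show box-only, immediate-screen, then corrected search", {
  out <- run_experiment("obs55")
  acts <- out$actions
  ph <- out$phases
  in_phase <- function(from, to) acts$action[acts$cycle >= from & acts$cycle < to]
  p1 <- in_phase(ph[["I.1"]], ph[["II"]])
  expect_true(any(grepl("^search\\(box", p1)))
  expect_false(any(grepl("^search\\(obj", p1)))     # I: no screen search
  p2 <- in_phase(ph[["II"]], ph[["III"]])
  expect_false(any(grepl("^search\\(box", p2)))     # II: immediate screen search
  expect_true(any(grepl("^search\\(obj\\(s1", p2)))
  expect_true(any(grepl("^grasp\\(obj\\(toy", p2)))
})

test_that("observation 64 blocks box reopening and walks screens in FIFO order", {
  out <- run_experiment("obs64")
  acts <- out$actions
  opens <- which(grepl("^open\\(", acts$action))
  expect_length(opens, 1L)                       # one opening, then LTB
  expect_lt(acts$cycle[opens], out$phases[["Ib"]])
  expect_identical(get_weight(out$model, "main", "watch", "openeff"), "BLOCKED")

  # phase Ib: immediate second-screen search, no first-screen search
  ib <- acts[acts$cycle >= out$phases[["Ib"]] & acts$cycle < out$phases[["II"]], ]
  expect_true(any(ib$action == "search(obj(s2,5))"))
  expect_false(any(grepl("s1", ib$action)))

  # phase II: searches in the exact order the screens were passed
  ii <- acts[acts$cycle >= out$phases[["II"]], ]
  searches <- ii$action[grepl("^search", ii$action)]
  expect_identical(searches, c("search(obj(s1,3))", "search(obj(s2,5))"))
})

test_that("golden traces regress cleanly and flag perturbations", {
  dir <- tempfile("goldens")
  write_goldens(dir, c("grasp", "track", "anotb"))
  rep <- regress(dir, c("grasp", "track", "anotb", "operant"))
  expect_setequal(rep$status[rep$experiment %in% c("grasp", "track", "anotb")], "equal")
  expect_identical(rep$status[rep$experiment == "operant"], "missing")

  # a perturbed configuration diffs
  m <- run_experiment("anotb", config = list(mode = "strong"))
  writeLines(format_trace(m$model), file.path(dir, "anotb.trc"))
  rep2 <- regress(dir, "anotb")
  row <- rep2[rep2$experiment == "anotb", ]
  expect_identical(row$status, "diff")
  expect_match(row$detail, "divergence")

  writeLines("1\tfire\tx y(1)", file.path(dir, "mystery.trc"))
  rep3 <- regress(dir, "grasp")
  expect_true(any(rep3$status == "unknown"))
})
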