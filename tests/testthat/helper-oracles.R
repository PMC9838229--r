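# Independent oracles and generators for property-style tests.
# The oracles deliberately avoid the code paths they check: the unification
# oracle enumerates ground substitutions; the deduction oracle enumerates
# the full cross-product of facts over guard slots without pruning.

# ---- ground-substitution oracle for unify -----------------------------------

# every ground subterm of t (the candidate values a matching substitution
# can take), plus a few base leaves
ground_subterms <- function(t) {
  out <- list()
  rec <- function(x) {
    if (is_ground(x)) out[[length(out) + 1L]] <<- x
    if (x$k == "c") for (ar in x$args) rec(ar)
  }
  rec(t)
  c(out, list(vt("a"), vt("b"), vt("1"), vt("2"), vt("3"), vt("4")))
}

# matching oracle: does any assignment of pattern variables to ground
# subterms of `b` (a ground term) make the pattern equal to b? Complete for
# matching because a variable's value under any matcher IS the subtree of b
# at the variable's position.
brute_match <- function(pattern, b, universe = ground_subterms(b)) {
  vars <- virtcog:::term_vars(pattern)
  if (length(vars) == 0L)
    return(identical(format_term(subst_apply(list(), pattern)), format_term(b)))
  idx <- rep(1L, length(vars))
  n <- length(universe)
  repeat {
    s <- stats::setNames(universe[idx], vars)
    ga <- subst_apply(s, pattern)
    if (is_ground(ga) && identical(format_term(ga), format_term(b))) return(TRUE)
    k <- 1L
    repeat {
      idx[k] <- idx[k] + 1L
      if (idx[k] <= n) break
      idx[k] <- 1L; k <- k + 1L
      if (k > length(vars)) return(FALSE)
    }
  }
}

# does the (resolved) substitution bind any variable to a term mentioning
# itself? (possible because there is deliberately no occurs-check)
subst_cyclic <- function(s) {
  any(vapply(names(s), function(nm) nm %in% virtcog:::term_vars(s[[nm]]), TRUE))
}

random_ground_term <- function(depth = 3L) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  if (depth <= 1L || stats::runif(1) < 0.4) {
    if (stats::runif(1) < 0.5) return(vt_atom(pick(c("a", "b"))))
    return(vt_int(sample.int(3L, 1L)))
  }
  if (stats::runif(1) < 0.5) vt_comp("f", random_ground_term(depth - 1L))
  else vt_comp("g", random_ground_term(depth - 1L), random_ground_term(depth - 1L))
}

# random term of bounded depth over a 4-symbol alphabet ({a,b}, f/1, g/2)
# plus ints, named variables and optional arithmetic offsets
random_term <- function(depth = 3L, vars = c("X", "Y"), arith = TRUE) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  if (depth <= 1L || stats::runif(1) < 0.4) {
    r <- stats::runif(1)
    if (r < 0.3) return(vt_atom(pick(c("a", "b"))))
    if (r < 0.5) return(vt_int(sample.int(3L, 1L)))
    v <- vt_var(pick(vars))
    if (arith && stats::runif(1) < 0.2) return(vt_plus(v, 1L))
    return(v)
  }
  if (stats::runif(1) < 0.5) vt_comp("f", random_term(depth - 1L, vars, arith))
  else vt_comp("g", random_term(depth - 1L, vars, arith), random_term(depth - 1L, vars, arith))
}

# ---- cross-product oracle for ist -------------------------------------------

# enumerate every assignment of distinct facts (newest first) to guard
# slots, keep those whose conjunctive unification succeeds; same output
# contract as ist()
brute_ist <- function(facts, rulebase) {
  if (length(facts) > 1L) {
    facts <- facts[order(vapply(facts, function(f) f$id, 0L), decreasing = TRUE)]
  }
  out <- list()
  for (im in rulebase) {
    g <- im$guards
    tuples <- list(integer(0))
    for (slot in seq_along(g)) {
      tuples <- do.call(c, lapply(tuples, function(tp)
        lapply(seq_along(facts), function(k) c(tp, k))))
    }
    for (tp in tuples) {
      if (anyDuplicated(tp)) next
      s <- list(); ok <- TRUE
      for (slot in seq_along(g)) {
        f <- facts[[tp[[slot]]]]
        if (f$name != g[[slot]]$name) { ok <- FALSE; break }
        s <- unify(g[[slot]]$pat, f$term, s)
        if (is.null(s)) { ok <- FALSE; break }
      }
      if (ok) out[[length(out) + 1L]] <-
          list(impl = im, s = s, ids = vapply(tp, function(k) facts[[k]]$id, 0L))
    }
  }
  out
}

deduction_sig <- function(deds) {
  vapply(deds, function(d)
    paste(d$impl$id, paste(d$ids, collapse = ","), virtcog:::subst_sig(d$s), sep = "|"), "")
}

# random rule bases (guards only; ist never looks at the instructions)
random_rulebase <- function(n_impl, guard_names = c("p", "q", "r")) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  rand_pat <- function() {
    args <- lapply(seq_len(2L), function(i) {
      r <- stats::runif(1)
      if (r < 0.35) vt_var(pick(c("X", "Y")))
      else if (r < 0.6) vt_atom(pick(c("a", "b", "c")))
      else vt_int(sample.int(3L, 1L))
    })
    vt_comp_list(pick(c("u", "w")), args)
  }
  lapply(seq_len(n_impl), function(k) {
    ng <- sample.int(2L, 1L)
    guards <- lapply(seq_len(ng), function(i) list(name = pick(guard_names), pat = rand_pat()))
    list(id = k, key = paste0("rand", k), guards = guards, ops = list(), choice = NULL)
  })
}

random_facts <- function(n_facts, names = c("p", "q", "r")) {
  pick <- function(x) x[[sample.int(length(x), 1L)]]
  lapply(seq_len(n_facts), function(k) {
    args <- lapply(seq_len(2L), function(i) {
      if (stats::runif(1) < 0.5) vt_atom(pick(c("a", "b", "c")))
      else vt_int(sample.int(3L, 1L))
    })
    list(id = k, name = pick(names), term = vt_comp_list(pick(c("u", "w")), args))
  })
}

vt_comp_list <- virtcog:::vt_comp_list

# tiny two-node model for substrate tests
toy_model <- function(config = list(), w = 1L, stream_q = "s") {
  m <- new_model(config)
  add_template(m, "p", "internal", "s", vt("p(X)"))
  add_template(m, "q", "internal", stream_q, vt("q(X)"))
  weight_init(m, "s", "p", "q", w)
  m
}
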