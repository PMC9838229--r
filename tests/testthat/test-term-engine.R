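# Term algebra: unification with named vs anonymous variables and
# eagerly evaluated position arithmetic.

test_that("unification handles structural match, clash, anonymity and arithmetic", {
  s <- unify(vt("obj(P,X)"), vt("obj(toy,3)"))
  expect_equal(format_term(s$P), "toy")
  expect_equal(format_term(s$X), "3")

  # anonymous bindings are consumed by the match, never recorded
  s2 <- unify(vt("see(obj(_,2))"), vt("see(obj(ball,2))"))
  expect_equal(length(s2), 0L)

  expect_null(unify(vt("obj(toy,2)"), vt("obj(ball,2)")))
  expect_null(unify(vt("f(a)"), vt("g(a)")))
  expect_null(unify(vt("f(a)"), vt("f(a,b)")))  # arity mismatch is failure, not error

  # arithmetic under an existing binding
  s3 <- unify(vt("obj(toy,X+1)"), vt("obj(toy,3)"), list(X = vt_int(2)))
  expect_equal(format_term(s3$X), "2")
  expect_null(unify(vt("obj(toy,X+1)"), vt("obj(toy,9)"), list(X = vt_int(2))))
  # and solved backwards when the base is free
  s4 <- unify(vt("look(obj(Q,X+1))"), vt("look(obj(s1,3))"))
  expect_equal(format_term(s4$X), "2")
})

test_that("substitution application evaluates arithmetic and is idempotent", {
  s <- list(X = vt_int(2))
  expect_equal(format_term(subst_apply(s, vt("look(obj(Q,X+1))"))), "look(obj(Q,3))")
  expect_equal(format_term(subst_apply(list(), vt("f(X,a)"))), "f(X,a)")
  expect_equal(format_term(subst_apply(list(P = vt_atom("toy")), vt("grasp(obj(P,4))"))),
               "grasp(obj(toy,4))")
  # idempotence of resulting substitutions
  t <- vt("g(f(X),Y)")
  s2 <- unify(t, vt("g(f(1),b)"))
  once <- subst_apply(s2, t)
  expect_identical(format_term(subst_apply(s2, once)), format_term(once))
})

test_that("groundness and freshening behave on all term kinds", {
  expect_true(is_ground(vt("obj(toy,3)")))
  expect_false(is_ground(vt("obj(P,3)")))
  expect_false(is_ground(vt("obj(toy,X+1)")))
  expect_false(is_ground(vt("f(_)")))

  g <- vt("grasp(obj(toy,3))")
  expect_identical(format_term(freshen(g)), format_term(g))

  fr <- freshen(vt("h(P,X,P)"))
  expect_identical(format_term(fr$args[[1]]), format_term(fr$args[[3]]))  # consistent renaming
  expect_false(format_term(fr$args[[1]]) == "P")

  an <- freshen(vt("f(_,_)"))
  expect_false(identical(format_term(an$args[[1]]), format_term(an$args[[2]])))
})

test_that("two anonymous occurrences never co-refer", {
  # f(_,_) must match two different arguments
  expect_false(is.null(unify(vt("f(_,_)"), vt("f(a,b)"))))
  # but one named variable must not
  expect_null(unify(vt("f(X,X)"), vt("f(a,b)")))
})

test_that("term literal syntax round-trips losslessly for ground terms", {
  for (txt in c("toy", "3", "obj(toy,3)", "image(box(f,toy,1))",
                "spot(obj(s1,empty,3))", "f(g(a,1),b)")) {
    expect_identical(format_term(vt(txt)), txt)
  }
  expect_error(vt("obj(toy,3"), "expected")
  expect_error(vt("X(a)"), "functor")
  expect_error(vt("f(a) b"), "trailing")
})

test_that("unify agrees with ground-substitution enumeration and is symmetric", {
  set.seed(41)
  for (k in 1:250) {
    a <- random_term(3L)
    b <- random_term(3L)
    got <- unify(a, b)
    rev <- unify(b, a)
    expect_identical(is.null(got), is.null(rev))  # symmetry of success
    if (!is.null(got) && !subst_cyclic(got)) {
      # the unifier really equalizes the terms
      expect_identical(format_term(subst_apply(got, a)), format_term(subst_apply(got, b)))
    }
  }
  # pattern-vs-ground agreement with the substitution-enumeration oracle
  checked <- 0L
  for (k in 1:250) {
    pat <- random_term(3L, arith = FALSE)
    g <- random_ground_term(3L)
    got <- !is.null(unify(pat, g))
    expect_identical(got, brute_match(pat, g),
                     label = sprintf("%s ~ %s", format_term(pat), format_term(g)))
    checked <- checked + 1L
  }
  expect_equal(checked, 250L)
})

test_that("a ground instance unifies with its own template", {
  set.seed(42)
  for (k in 1:60) {
    t <- random_term(3L, arith = FALSE)
    s <- unify(t, subst_apply(list(X = vt_atom("a"), Y = vt_int(2)), t))
    inst <- subst_apply(list(X = vt_atom("a"), Y = vt_int(2)), t)
    if (is_ground(inst)) expect_false(is.null(s))
  }
})
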