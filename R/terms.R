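# First-order term algebra: atoms, integers, named/anonymous variables,
# compounds and small position arithmetic (X+k) on the 1-D spatial axis.
#
# Terms are tagged lists:
#   list(k = "a", v = <chr>)            atom
#   list(k = "i", v = <int>)            integer (axis position)
#   list(k = "v", v = <chr>)            named variable (uppercase)
#   list(k = "_", v = <int id>)         anonymous variable, pairwise distinct
#   list(k = "c", f = <chr>, args = <list>)  compound
#   list(k = "+", base = <term>, off = <int>)  arithmetic offset
#
# Anonymous variables may be bound *during* a unification but the binding is
# consumed by the match and never recorded in the resulting substitution:
# this is the formal footing of "weak" plasticity (a pathway instantiated
# once cannot re-instantiate differently).

.vcog <- new.env(parent = emptyenv())
.vcog$anon_id <- 0L
.vcog$fresh_id <- 0L

#' Construct terms
#'
#' Low-level constructors for the symbolic term algebra used throughout the
#' package. Most code builds terms from text with [vt()] instead.
#'
#' @param x atom name (lowercase) or variable name (uppercase first letter).
#' @param v integer position on the one-dimensional axis.
#' @param f functor name.
#' @param ... argument terms of a compound.
#' @param base term to which an integer offset is added.
#' @param off integer offset (e.g. the `+1` of `X+1`).
#' @return A term object of class `vcog_term`.
#' @examples
#' vt_comp("obj", vt_atom("toy"), vt_int(3))
#' vt_plus(vt_var("X"), 1)
#' @name term-constructors
NULL

#' @rdname term-constructors
#' @export
vt_atom <- function(x) structure(list(k = "a", v = x), class = "vcog_term")

#' @rdname term-constructors
#' @export
vt_int <- function(v) structure(list(k = "i", v = as.integer(v)), class = "vcog_term")

#' @rdname term-constructors
#' @export
vt_var <- function(x) structure(list(k = "v", v = x), class = "vcog_term")

#' @rdname term-constructors
#' @export
vt_anon <- function() {
  .vcog$anon_id <- .vcog$anon_id + 1L
  structure(list(k = "_", v = .vcog$anon_id), class = "vcog_term")
}

#' @rdname term-constructors
#' @export
vt_comp <- function(f, ...) {
  structure(list(k = "c", f = f, args = list(...)), class = "vcog_term")
}

#' @rdname term-constructors
#' @export
vt_plus <- function(base, off) {
  structure(list(k = "+", base = base, off = as.integer(off)), class = "vcog_term")
}

vt_comp_list <- function(f, args) {
  structure(list(k = "c", f = f, args = args), class = "vcog_term")
}

## ---- parsing ---------------------------------------------------------------

# Grammar (whitespace-insensitive):
#   term  := prim [ "+" int ]
#   prim  := int | "_" | name [ "(" term { "," term } ")" ]
#   name  := atom (lowercase-led) | variable (uppercase-led)

vt_tokenize <- function(text) {
  pat <- "[A-Za-z][A-Za-z0-9_]*|[0-9]+|[(),+_]|\\s+"
  out <- character(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    m <- regexpr(pat, substr(text, pos, n))
    if (m != 1L) stop(sprintf("bad character in term at '%s'", substr(text, pos, min(n, pos + 10L))))
    len <- attr(m, "match.length")
    tok <- substr(text, pos, pos + len - 1L)
    if (!grepl("^\\s+$", tok)) out <- c(out, tok)
    pos <- pos + len
  }
  out
}

#' Parse a term from its literal syntax
#'
#' Lowercase identifiers are atoms, uppercase identifiers named variables,
#' `_` an anonymous variable (fresh and pairwise distinct at every
#' occurrence), `f(a,B,_)` a compound, and `X+1` an integer offset on the
#' axis. Round-trip through [format_term()] is lossless for ground terms.
#'
#' @param text a single term in literal syntax, e.g. `"see(obj(P,X+1))"`.
#' @return a `vcog_term`.
#' @examples
#' vt("grasp(obj(toy,3))")
#' format_term(vt("look(obj(Q,X+1))"))
#' @export
vt <- function(text) {
  toks <- vt_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  peek <- function() if (st$i <= length(toks)) toks[[st$i]] else NA_character_
  take <- function() { t <- peek(); st$i <- st$i + 1L; t }
  expect <- function(x) {
    t <- take()
    if (is.na(t) || t != x) stop(sprintf("expected '%s' in term '%s'", x, text))
    t
  }
  prim <- function() {
    t <- take()
    if (is.na(t)) stop(sprintf("unexpected end of term '%s'", text))
    if (grepl("^[0-9]+$", t)) return(vt_int(as.integer(t)))
    if (t == "_") return(vt_anon())
    if (!grepl("^[A-Za-z]", t)) stop(sprintf("unexpected token '%s' in '%s'", t, text))
    is_var <- grepl("^[A-Z]", t)
    if (identical(peek(), "(")) {
      take()
      args <- list(term())
      while (identical(peek(), ",")) { take(); args <- c(args, list(term())) }
      expect(")")
      if (is_var) stop(sprintf("variable '%s' used as functor in '%s'", t, text))
      return(vt_comp_list(t, args))
    }
    if (is_var) vt_var(t) else vt_atom(t)
  }
  term <- function() {
    base <- prim()
    if (identical(peek(), "+")) {
      take()
      offt <- take()
      if (is.na(offt) || !grepl("^[0-9]+$", offt)) stop(sprintf("offset must be an integer in '%s'", text))
      if (base$k == "i") return(vt_int(base$v + as.integer(offt)))
      return(vt_plus(base, as.integer(offt)))
    }
    base
  }
  out <- term()
  if (st$i <= length(toks)) stop(sprintf("trailing tokens in term '%s'", text))
  out
}

#' Render a term in its literal syntax
#'
#' @param t a `vcog_term`.
#' @return a character scalar.
#' @export
format_term <- function(t) {
  switch(t$k,
    "a" = t$v,
    "i" = as.character(t$v),
    "v" = t$v,
    "_" = paste0("_", t$v),
    "c" = paste0(t$f, "(", paste(vapply(t$args, format_term, ""), collapse = ","), ")"),
    "+" = paste0(format_term(t$base), "+", t$off),
    stop("unknown term kind")
  )
}

#' @export
print.vcog_term <- function(x, ...) {
  cat(format_term(x), "\n")
  invisible(x)
}

#' @export
format.vcog_term <- function(x, ...) format_term(x)

term_equal <- function(a, b) identical(format_term(a), format_term(b))

## ---- substitutions ---------------------------------------------------------

# A substitution is a named list mapping named-variable names to terms.
# Invariants: idempotent (values fully resolved), never binds anonymous
# variables. The empty substitution is list().

# There is no occurs-check (circuit guards are shallow and the DSL cannot
# build cyclic terms), so walking and resolution guard against reference
# cycles instead of recursing into them.
walk_term <- function(t, bnd) {
  seen <- character(0)
  repeat {
    key <- switch(t$k, "v" = t$v, "_" = paste0("_", t$v), NULL)
    if (is.null(key) || key %in% seen) break
    nxt <- bnd[[key]]
    if (is.null(nxt)) break
    seen <- c(seen, key)
    t <- nxt
  }
  if (t$k == "+") {
    b <- walk_term(t$base, bnd)
    if (b$k == "i") return(vt_int(b$v + t$off))
    if (b$k == "+") return(vt_plus(b$base, b$off + t$off))
    return(vt_plus(b, t$off))
  }
  t
}

resolve_term <- function(t, bnd, seen = character(0)) {
  key <- switch(t$k, "v" = t$v, "_" = paste0("_", t$v), NULL)
  if (!is.null(key)) {
    if (key %in% seen) return(t)   # cyclic binding: leave the variable in place
    if (!is.null(bnd[[key]])) return(resolve_term(bnd[[key]], bnd, c(seen, key)))
    return(t)
  }
  if (t$k == "c") { t$args <- lapply(t$args, resolve_term, bnd = bnd, seen = seen); return(t) }
  if (t$k == "+") {
    b <- resolve_term(t$base, bnd, seen)
    if (b$k == "i") return(vt_int(b$v + t$off))
    if (b$k == "+") return(vt_plus(b$base, b$off + t$off))
    t$base <- b
  }
  t
}

has_anon <- function(t) {
  switch(t$k,
    "_" = TRUE,
    "c" = any(vapply(t$args, has_anon, TRUE)),
    "+" = has_anon(t$base),
    FALSE
  )
}

unify_walked <- function(a, b, bnd) {
  a <- walk_term(a, bnd)
  b <- walk_term(b, bnd)
  akey <- switch(a$k, "v" = a$v, "_" = paste0("_", a$v), NULL)
  bkey <- switch(b$k, "v" = b$v, "_" = paste0("_", b$v), NULL)
  if (!is.null(akey) && !is.null(bkey) && akey == bkey) return(bnd)
  if (!is.null(akey)) { bnd[[akey]] <- b; return(bnd) }
  if (!is.null(bkey)) { bnd[[bkey]] <- a; return(bnd) }
  if (a$k == "+" && b$k == "i") {
    base <- walk_term(a$base, bnd)  # unbound var or anon here
    return(unify_walked(base, vt_int(b$v - a$off), bnd))
  }
  if (b$k == "+" && a$k == "i") return(unify_walked(b, a, bnd))
  if (a$k == "+" && b$k == "+") {
    if (a$off != b$off) return(NULL)
    return(unify_walked(a$base, b$base, bnd))
  }
  if (a$k == "+" || b$k == "+") return(NULL)
  if (a$k != b$k) return(NULL)
  if (a$k %in% c("a", "i")) return(if (identical(a$v, b$v)) bnd else NULL)
  if (a$k == "c") {
    if (a$f != b$f || length(a$args) != length(b$args)) return(NULL)
    for (i in seq_along(a$args)) {
      bnd <- unify_walked(a$args[[i]], b$args[[i]], bnd)
      if (is.null(bnd)) return(NULL)
    }
    return(bnd)
  }
  NULL
}

#' Unify two terms under a substitution
#'
#' Returns the most general extension of `s` under which `a` and `b` are
#' equal, or `NULL` when no unifier exists (failure is a value, never an
#' error). Bindings taken by anonymous variables are consumed by the match
#' and are not recorded in the result. Arithmetic sub-terms are evaluated
#' eagerly when their base is (or becomes) an integer; `X+1` against `3`
#' also solves backwards, binding `X` to `2`. There is no occurs-check:
#' circuit guards are shallow.
#'
#' @param a,b terms.
#' @param s an existing substitution (named list), default empty.
#' @return a substitution (named list) or `NULL` on failure.
#' @examples
#' unify(vt("obj(P,X)"), vt("obj(toy,3)"))
#' unify(vt("obj(toy,X+1)"), vt("obj(toy,3)"), list(X = vt_int(2)))
#' unify(vt("obj(toy,2)"), vt("obj(ball,2)"))  # NULL
#' @export
unify <- function(a, b, s = list()) {
  bnd <- s
  bnd <- unify_walked(a, b, bnd)
  if (is.null(bnd)) return(NULL)
  out <- list()
  for (key in names(bnd)) {
    if (startsWith(key, "_")) next  # anonymous: consumed, never recorded
    val <- resolve_term(bnd[[key]], bnd)
    if (has_anon(val)) next  # value constrained only by an anon: no reusable binding
    out[[key]] <- val
  }
  out
}

#' Apply a substitution to a term
#'
#' Replaces bound named variables and evaluates arithmetic whose base has
#' become an integer; unbound variables pass through unchanged.
#'
#' @param s substitution (named list of terms).
#' @param t a term.
#' @return the instantiated term.
#' @examples
#' subst_apply(list(X = vt_int(2)), vt("look(obj(Q,X+1))"))
#' @export
subst_apply <- function(s, t) resolve_term(t, s)

#' Is a term ground?
#'
#' Ground terms contain no variables (named or anonymous) and no
#' unevaluated arithmetic. Only ground terms may enter the associative
#' store or short-term memories.
#'
#' @param t a term.
#' @return `TRUE` or `FALSE`.
#' @export
is_ground <- function(t) {
  switch(t$k,
    "a" = TRUE, "i" = TRUE,
    "v" = FALSE, "_" = FALSE, "+" = FALSE,
    "c" = all(vapply(t$args, is_ground, TRUE)),
    FALSE
  )
}

term_vars <- function(t) {
  switch(t$k,
    "v" = t$v,
    "c" = unique(unlist(lapply(t$args, term_vars))),
    "+" = term_vars(t$base),
    character(0)
  )
}

#' Rename a term's variables apart
#'
#' Returns `t` with every named variable consistently renamed to an unused
#' name and every anonymous variable replaced by a fresh distinct one;
#' structure is preserved and ground terms come back identical. Rule
#' instances are freshened before each deduction so that variables scope
#' per compiled implication instance.
#'
#' @param t a term.
#' @return a term.
#' @export
freshen <- function(t) {
  map <- new.env(parent = emptyenv())
  fr <- function(t) {
    switch(t$k,
      "v" = {
        if (is.null(map[[t$v]])) {
          .vcog$fresh_id <- .vcog$fresh_id + 1L
          map[[t$v]] <- vt_var(paste0(t$v, "_G", .vcog$fresh_id))
        }
        map[[t$v]]
      },
      "_" = vt_anon(),
      "c" = { t$args <- lapply(t$args, fr); t },
      "+" = { t$base <- fr(t$base); t },
      t
    )
  }
  fr(t)
}
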