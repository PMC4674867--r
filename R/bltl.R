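#' Bounded linear temporal logic (BLTL) formulas
#'
#' BLTL is propositional logic over trace states extended with temporal
#' operators that carry integer step bounds: `phi1 U[d] phi2` (bounded
#' until), `F[d] phi` (eventually within d steps) and `G[d] phi` (always
#' for the next d steps).  Because every temporal operator is bounded, the
#' truth of a formula on an infinite execution is decidable from a finite
#' prefix whose length is [required_horizon()].
#'
#' Formulas are finite abstract syntax trees.  Leaves are either named
#' atomic propositions (resolved against a trace's label set), inline
#' numeric comparisons over trace variables (`pro > 5`), or the constant
#' `true`.
#'
#' @param text a single character string in the concrete syntax described
#'   under [parse_formula()].
#' @return an object of class `"bltl"`: a nested list with a `kind` field
#'   (`"ATOM"`, `"TRUE"`, `"NOT"`, `"AND"`, `"OR"`, `"UNTIL"`) and, for
#'   temporal nodes, an integer `bound`.
#' @seealso [parse_formula()], [bltl_eval()], [required_horizon()],
#'   [rewrite_derived()]
#' @examples
#' f <- bltl("D_L -> F[5](I & F[8](N))")
#' required_horizon(f)
#' @export
bltl <- function(text) parse_formula(text)

## ---- AST constructors -----------------------------------------------------

bltl_node <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "bltl")
}

bltl_atom <- function(name) bltl_node("ATOM", name = name)

bltl_cmp <- function(var, op, value) {
  stopifnot(op %in% c("<", "<=", ">", ">=", "=="))
  bltl_node("ATOM", name = paste(var, op, format(value, digits = 15)),
            cmp = list(var = var, op = op, value = value))
}

bltl_true <- function() bltl_node("TRUE")

bltl_not <- function(x) bltl_node("NOT", child = x)
bltl_and <- function(l, r) bltl_node("AND", left = l, right = r)
bltl_or  <- function(l, r) bltl_node("OR",  left = l, right = r)

bltl_until <- function(bound, l, r) {
  bound <- check_bound(bound)
  bltl_node("UNTIL", bound = bound, left = l, right = r)
}
bltl_finally  <- function(bound, x) {
  bltl_node("FINALLY", bound = check_bound(bound), child = x)
}
bltl_globally <- function(bound, x) {
  bltl_node("GLOBALLY", bound = check_bound(bound), child = x)
}

check_bound <- function(bound) {
  if (length(bound) != 1L || is.na(bound) || bound < 0 ||
      bound != as.integer(bound))
    stop("temporal bound must be a single nonnegative integer, got ",
         deparse(bound), call. = FALSE)
  as.integer(bound)
}

is_temporal <- function(kind) kind %in% c("UNTIL", "FINALLY", "GLOBALLY")

## ---- concrete syntax ------------------------------------------------------

#' Parse a BLTL formula from its text syntax
#'
#' The concrete syntax uses C-like operators:
#' \itemize{
#'   \item atoms: identifiers (`I`, `D_L`, ...), the constant `true`, or
#'     inline comparisons `var < c`, `var <= c`, `var > c`, `var >= c`,
#'     `var == c` with a numeric literal `c`;
#'   \item `!p` negation, `p & q` conjunction, `p | q` disjunction,
#'     `p -> q` implication (desugared to `!p | q` at parse time);
#'   \item `p U[d] q` bounded until, `F[d] p` bounded eventually,
#'     `G[d] p` bounded always, with a nonnegative integer bound `d`.
#' }
#' Precedence, tightest first: `!`/`F`/`G`, `U`, `&`, `|`, `->`; `U` and
#' `->` associate to the right; parentheses override.
#'
#' @param text a single character string.
#' @return a `"bltl"` formula object.
#' @examples
#' parse_formula("!a U[3] b & c")   # ((!a) U[3] b) & c
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("formula text must be a nonempty string", call. = FALSE)
  toks <- bltl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  f <- p_implies(st)
  tk <- peek_tok(st)
  if (tk$type != "EOF")
    parse_fail(tk, "unexpected trailing input")
  f
}

bltl_tokenize <- function(text) {
  specs <- list(
    c("WS",     "^\\s+"),
    c("ARROW",  "^->"),
    c("LE",     "^<="), c("GE", "^>="), c("EQ", "^=="),
    c("LT",     "^<"),  c("GT", "^>"),
    c("NOT",    "^!"),  c("AND", "^&"), c("OR", "^\\|"),
    c("LPAREN", "^\\("), c("RPAREN", "^\\)"),
    c("LBRACK", "^\\["), c("RBRACK", "^\\]"),
    c("NUMBER", "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?"),
    c("IDENT",  "^[A-Za-z_][A-Za-z0-9_]*")
  )
  out <- list()
  rest <- text
  at <- 1L
  while (nzchar(rest)) {
    hit <- FALSE
    for (sp in specs) {
      m <- regmatches(rest, regexpr(sp[2], rest))
      if (length(m) == 1L && nzchar(m)) {
        if (sp[1] != "WS")
          out[[length(out) + 1L]] <- list(type = sp[1], value = m, at = at)
        at <- at + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        hit <- TRUE
        break
      }
    }
    if (!hit)
      stop(sprintf("BLTL syntax error at position %d: unexpected character '%s'",
                   at, substring(rest, 1L, 1L)), call. = FALSE)
  }
  out[[length(out) + 1L]] <- list(type = "EOF", value = "", at = at)
  out
}

peek_tok <- function(st) st$toks[[st$pos]]
next_tok <- function(st) {
  tk <- st$toks[[st$pos]]
  st$pos <- st$pos + 1L
  tk
}
parse_fail <- function(tk, msg) {
  stop(sprintf("BLTL syntax error at position %d: %s (near '%s')",
               tk$at, msg, tk$value), call. = FALSE)
}

p_implies <- function(st) {
  lhs <- p_or(st)
  if (peek_tok(st)$type == "ARROW") {
    next_tok(st)
    rhs <- p_implies(st)          # right-associative
    return(bltl_or(bltl_not(lhs), rhs))
  }
  lhs
}

p_or <- function(st) {
  lhs <- p_and(st)
  while (peek_tok(st)$type == "OR") {
    next_tok(st)
    lhs <- bltl_or(lhs, p_and(st))
  }
  lhs
}

p_and <- function(st) {
  lhs <- p_until(st)
  while (peek_tok(st)$type == "AND") {
    next_tok(st)
    lhs <- bltl_and(lhs, p_until(st))
  }
  lhs
}

p_until <- function(st) {
  lhs <- p_unary(st)
  tk <- peek_tok(st)
  if (tk$type == "IDENT" && tk$value == "U") {
    next_tok(st)
    d <- p_bound(st)
    rhs <- p_until(st)            # right-associative
    return(bltl_until(d, lhs, rhs))
  }
  lhs
}

p_unary <- function(st) {
  tk <- peek_tok(st)
  if (tk$type == "NOT") {
    next_tok(st)
    return(bltl_not(p_unary(st)))
  }
  if (tk$type == "IDENT" && tk$value %in% c("F", "G") &&
      st$toks[[st$pos + 1L]]$type == "LBRACK") {
    next_tok(st)
    d <- p_bound(st)
    x <- p_unary(st)
    return(if (tk$value == "F") bltl_finally(d, x) else bltl_globally(d, x))
  }
  p_primary(st)
}

p_bound <- function(st) {
  tk <- next_tok(st)
  if (tk$type != "LBRACK") parse_fail(tk, "expected '[' before temporal bound")
  num <- next_tok(st)
  if (num$type != "NUMBER") parse_fail(num, "expected an integer bound")
  val <- suppressWarnings(as.numeric(num$value))
  if (is.na(val) || val < 0 || val != round(val))
    parse_fail(num, "temporal bound must be a nonnegative integer")
  cl <- next_tok(st)
  if (cl$type != "RBRACK") parse_fail(cl, "expected ']' after temporal bound")
  as.integer(val)
}

p_primary <- function(st) {
  tk <- next_tok(st)
  if (tk$type == "LPAREN") {
    f <- p_implies(st)
    cl <- next_tok(st)
    if (cl$type != "RPAREN") parse_fail(cl, "expected ')'")
    return(f)
  }
  if (tk$type == "IDENT") {
    if (tk$value == "true") return(bltl_true())
    op_tk <- peek_tok(st)
    if (op_tk$type %in% c("LT", "LE", "GT", "GE", "EQ")) {
      next_tok(st)
      num <- next_tok(st)
      if (num$type != "NUMBER") parse_fail(num, "expected a numeric literal")
      op <- c(LT = "<", LE = "<=", GT = ">", GE = ">=", EQ = "==")[[op_tk$type]]
      return(bltl_cmp(tk$value, op, as.numeric(num$value)))
    }
    return(bltl_atom(tk$value))
  }
  parse_fail(tk, "expected an atom, 'true', '!', or '('")
}

#' Render a formula back to its text syntax
#'
#' The output is fully parenthesized so that re-parsing it yields an
#' identical syntax tree.
#'
#' @param formula a `"bltl"` object.
#' @return a character string.
#' @export
unparse <- function(formula) {
  stopifnot(inherits(formula, "bltl"))
  switch(formula$kind,
    "TRUE"   = "true",
    ATOM     = formula$name,
    NOT      = paste0("!", wrap(formula$child)),
    AND      = paste0(wrap(formula$left), " & ", wrap(formula$right)),
    OR       = paste0(wrap(formula$left), " | ", wrap(formula$right)),
    UNTIL    = paste0(wrap(formula$left), " U[", formula$bound, "] ",
                      wrap(formula$right)),
    FINALLY  = paste0("F[", formula$bound, "] ", wrap(formula$child)),
    GLOBALLY = paste0("G[", formula$bound, "] ", wrap(formula$child)),
    stop("unknown node kind: ", formula$kind)
  )
}

wrap <- function(f) {
  if (f$kind %in% c("ATOM", "TRUE")) {
    if (!is.null(f$cmp)) return(paste0("(", unparse(f), ")"))
    return(unparse(f))
  }
  paste0("(", unparse(f), ")")
}

#' @export
print.bltl <- function(x, ...) {
  cat("BLTL formula: ", unparse(x), "\n", sep = "")
  cat("  horizon:", required_horizon(x), "steps\n")
  invisible(x)
}

#' @export
format.bltl <- function(x, ...) unparse(x)

## ---- structural operations ------------------------------------------------

#' Number of trace steps needed to decide a formula
#'
#' Every temporal operator in BLTL carries a finite bound, so a formula's
#' truth at position `i` of a trace is determined by the states
#' `s_i, ..., s_{i+h}` where `h` is the value returned here: 0 for atoms,
#' the maximum over children for boolean connectives, and `d` plus the
#' children's maximum for a bound-`d` temporal operator.
#'
#' @param formula a `"bltl"` object.
#' @return a nonnegative integer.
#' @examples
#' required_horizon(bltl("F[3](a & F[2] b)"))  # 5
#' @export
required_horizon <- function(formula) {
  stopifnot(inherits(formula, "bltl"))
  switch(formula$kind,
    "TRUE"   = 0L,
    ATOM     = 0L,
    NOT      = required_horizon(formula$child),
    AND      = max(required_horizon(formula$left), required_horizon(formula$right)),
    OR       = max(required_horizon(formula$left), required_horizon(formula$right)),
    UNTIL    = formula$bound + max(required_horizon(formula$left),
                                   required_horizon(formula$right)),
    FINALLY  = formula$bound + required_horizon(formula$child),
    GLOBALLY = formula$bound + required_horizon(formula$child)
  )
}

#' Rewrite derived temporal operators into bounded until
#'
#' Applies the identities `F[d] p == true U[d] p` and
#' `G[d] p == !(true U[d] !p)` recursively, so the result contains only
#' atoms, boolean connectives and bounded until.  The rewrite preserves
#' both satisfaction on every trace and the required horizon.
#'
#' @param formula a `"bltl"` object.
#' @return an equivalent `"bltl"` object free of `F`/`G` nodes.
#' @export
rewrite_derived <- function(formula) {
  stopifnot(inherits(formula, "bltl"))
  switch(formula$kind,
    "TRUE"   = formula,
    ATOM     = formula,
    NOT      = bltl_not(rewrite_derived(formula$child)),
    AND      = bltl_and(rewrite_derived(formula$left), rewrite_derived(formula$right)),
    OR       = bltl_or(rewrite_derived(formula$left), rewrite_derived(formula$right)),
    UNTIL    = bltl_until(formula$bound, rewrite_derived(formula$left),
                          rewrite_derived(formula$right)),
    FINALLY  = bltl_until(formula$bound, bltl_true(),
                          rewrite_derived(formula$child)),
    GLOBALLY = bltl_not(bltl_until(formula$bound, bltl_true(),
                                   bltl_not(rewrite_derived(formula$child))))
  )
}

## ---- evaluation -----------------------------------------------------------

#' Evaluate a BLTL formula on a finite trace
#'
#' Implements the standard finite-trace semantics: an atom holds at
#' position `i` iff it labels state `s_i`; `phi1 U[d] phi2` holds at `i`
#' iff there is an `l` with `0 <= l <= d` such that `phi2` holds at
#' `i + l` and `phi1` holds at every `i + j` for `0 <= j < l` (so `l = 0`
#' is admitted and `F[0] p` is `p`).  Evaluation refuses traces shorter
#' than `position + required_horizon(formula)`: a truth value is never
#' fabricated from an undecidable prefix.
#'
#' Internally the evaluator fills a bottom-up table of truth values per
#' (subformula, position), linear in formula size times trace length; the
#' package's tests cross-check it exhaustively against a naive recursive
#' evaluator.
#'
#' @param trace an `"smc_trace"` object, see [smc_trace()].
#' @param formula a `"bltl"` object.
#' @param position 0-based evaluation position on the trace (default 0).
#' @return `TRUE` or `FALSE`.
#' @export
bltl_eval <- function(trace, formula, position = 0L) {
  stopifnot(inherits(trace, "smc_trace"), inherits(formula, "bltl"))
  k <- trace_length(trace) - 1L
  position <- as.integer(position)
  if (position < 0L || position > k)
    stop("position must lie on the trace (0..", k, ")", call. = FALSE)
  h <- required_horizon(formula)
  if (position + h > k)
    stop(sprintf(paste0("trace too short: deciding the formula at position %d ",
                        "needs %d states but the trace has %d"),
                 position, position + h + 1L, k + 1L), call. = FALSE)
  tab <- bltl_table(trace, formula, k)
  unname(tab[position + 1L])
}

## truth vector of `formula` over positions 0..k; entries at positions whose
## horizon exceeds the trace end are not meaningful and never read for a
## position satisfying the caller's precondition
bltl_table <- function(trace, formula, k) {
  switch(formula$kind,
    "TRUE" = rep(TRUE, k + 1L),
    ATOM   = atom_truth(trace, formula),
    NOT    = !bltl_table(trace, formula$child, k),
    AND    = bltl_table(trace, formula$left, k) & bltl_table(trace, formula$right, k),
    OR     = bltl_table(trace, formula$left, k) | bltl_table(trace, formula$right, k),
    UNTIL  = {
      v1 <- bltl_table(trace, formula$left, k)
      v2 <- bltl_table(trace, formula$right, k)
      d <- formula$bound
      out <- logical(k + 1L)
      for (i in 0:k) {
        acc <- FALSE
        for (l in 0:min(d, k - i)) {
          if (v2[i + l + 1L]) { acc <- TRUE; break }
          if (!v1[i + l + 1L]) break   # phi1 broken before phi2 arrived
        }
        out[i + 1L] <- acc
      }
      out
    },
    FINALLY  = bltl_table(trace, rewrite_derived(formula), k),
    GLOBALLY = bltl_table(trace, rewrite_derived(formula), k)
  )
}

atom_truth <- function(trace, atom) {
  if (!is.null(atom$cmp)) {
    v <- trace$values[[atom$cmp$var]]
    if (is.null(v))
      stop("trace has no variable '", atom$cmp$var, "'", call. = FALSE)
    return(switch(atom$cmp$op,
      "<"  = v <  atom$cmp$value,
      "<=" = v <= atom$cmp$value,
      ">"  = v >  atom$cmp$value,
      ">=" = v >= atom$cmp$value,
      "==" = v == atom$cmp$value))
  }
  if (!atom$name %in% colnames(trace$labels))
    stop("atomic proposition '", atom$name,
         "' is not registered on this trace", call. = FALSE)
  trace$labels[, atom$name]
}

## reference evaluator: direct recursion on the semantics, used as the
## oracle in tests (deliberately naive, no memoization)
bltl_eval_naive <- function(trace, formula, position = 0L) {
  k <- trace_length(trace) - 1L
  i <- as.integer(position)
  rec <- function(f, i) {
    switch(f$kind,
      "TRUE" = TRUE,
      ATOM   = unname(atom_truth(trace, f)[i + 1L]),
      NOT    = !rec(f$child, i),
      AND    = rec(f$left, i) && rec(f$right, i),
      OR     = rec(f$left, i) || rec(f$right, i),
      UNTIL  = {
        for (l in 0:min(f$bound, k - i)) {
          if (rec(f$right, i + l)) {
            ok <- TRUE
            for (j in seq_len(l) - 1L)
              if (!rec(f$left, i + j)) { ok <- FALSE; break }
            if (ok) return(TRUE)
          }
        }
        FALSE
      },
      FINALLY  = rec(rewrite_derived(f), i),
      GLOBALLY = rec(rewrite_derived(f), i)
    )
  }
  rec(formula, i)
}

#' Read BLTL formulas from a text file
#'
#' One formula per line; blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path file path.
#' @return a list of `"bltl"` objects.
#' @export
read_formulas <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_formula)
}
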