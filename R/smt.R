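## A small satisfiability checker for quantifier-free linear real
## arithmetic (QF_LRA), sufficient for verifying decision traces:
## formulas are rendered in an SMT-LIB 2 subset, parsed back into an AST,
## and decided by DPLL search over the Boolean abstraction with a
## Fourier-Motzkin feasibility check of the selected arithmetic literals.
## Named (tracked) assertions support unsat-core extraction.
##
## This is the solver channel of the dual-channel verifier; the direct
## Boolean evaluator in constraints.R never calls into this file.

## ---- s-expression parsing -------------------------------------------------

tokenize_sexpr <- function(text) {
  text <- gsub(";[^\n]*", " ", text)            # strip comments
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

parse_sexprs <- function(text) {
  toks <- tokenize_sexpr(text)
  pos <- 1L
  parse_one <- function() {
    if (pos > length(toks)) stop_fdt("unexpected end of SMT script")
    t <- toks[pos]; pos <<- pos + 1L
    if (t == "(") {
      items <- list()
      while (pos <= length(toks) && toks[pos] != ")") {
        items[[length(items) + 1L]] <- parse_one()
      }
      if (pos > length(toks)) stop_fdt("unbalanced parenthesis in SMT script")
      pos <<- pos + 1L                          # consume ")"
      return(items)
    }
    if (t == ")") stop_fdt("unexpected ')' in SMT script")
    t
  }
  out <- list()
  while (pos <= length(toks)) out[[length(out) + 1L]] <- parse_one()
  out
}

is_num_token <- function(t) {
  is.character(t) && length(t) == 1 && grepl("^-?[0-9]+(\\.[0-9]+)?$", t)
}

#' Parse an SMT-LIB 2 script (QF_LRA subset)
#'
#' Supports `set-logic`, `declare-const` (Real/Bool), `assert` with
#' optional `(! expr :named id)` tracking annotations, and `check-sat`.
#'
#' @param text SMT-LIB script text.
#' @return List with `declarations` (named character vector of sorts) and
#'   `assertions` (list of `list(ast, name)`).
#' @keywords internal
parse_smt_script <- function(text) {
  forms <- parse_sexprs(text)
  decls <- character(0)
  asserts <- list()
  for (f in forms) {
    if (!is.list(f) || length(f) == 0) next
    head <- f[[1]]
    if (identical(head, "set-logic") || identical(head, "check-sat") ||
        identical(head, "get-unsat-core") || identical(head, "get-model")) next
    if (identical(head, "declare-const")) {
      decls[[f[[2]]]] <- f[[3]]
    } else if (identical(head, "assert")) {
      body <- f[[2]]
      name <- NULL
      if (is.list(body) && identical(body[[1]], "!")) {
        stopifnot(identical(body[[3]], ":named"))
        name <- body[[4]]
        body <- body[[2]]
      }
      asserts[[length(asserts) + 1L]] <- list(ast = body, name = name)
    } else {
      stop_fdt("unsupported SMT command: ", as.character(head))
    }
  }
  list(declarations = decls, assertions = asserts)
}

## ---- linear arithmetic ----------------------------------------------------

CMP_OPS <- c("=", ">", ">=", "<", "<=")

## linear expression of an AST -> list(coef = named numeric, const)
lin_expr <- function(ast) {
  if (is_num_token(ast)) return(list(coef = numeric(0), const = as.numeric(ast)))
  if (is.character(ast)) {
    return(list(coef = stats::setNames(1, ast), const = 0))
  }
  op <- ast[[1]]
  args <- ast[-1]
  combine <- function(a, b, sgn) {
    nm <- union(names(a$coef), names(b$coef))
    co <- stats::setNames(rep(0, length(nm)), nm)
    co[names(a$coef)] <- co[names(a$coef)] + a$coef
    co[names(b$coef)] <- co[names(b$coef)] + sgn * b$coef
    list(coef = co[co != 0], const = a$const + sgn * b$const)
  }
  if (identical(op, "+")) {
    out <- lin_expr(args[[1]])
    for (a in args[-1]) out <- combine(out, lin_expr(a), 1)
    return(out)
  }
  if (identical(op, "-")) {
    if (length(args) == 1) {
      e <- lin_expr(args[[1]])
      return(list(coef = -e$coef, const = -e$const))
    }
    out <- lin_expr(args[[1]])
    for (a in args[-1]) out <- combine(out, lin_expr(a), -1)
    return(out)
  }
  if (identical(op, "*")) {
    es <- lapply(args, lin_expr)
    isconst <- vapply(es, function(e) length(e$coef) == 0, logical(1))
    if (sum(!isconst) > 1) stop_fdt("non-linear product in QF_LRA formula")
    k <- prod(vapply(es[isconst], `[[`, 0, "const"))
    if (all(isconst)) return(list(coef = numeric(0), const = k))
    e <- es[[which(!isconst)]]
    return(list(coef = k * e$coef, const = k * e$const))
  }
  stop_fdt("unsupported arithmetic operator: ", as.character(op))
}

## arithmetic atom -> normalized literal(s): sum(coef*x) <= rhs (strict flag)
## truth = TRUE keeps the atom, FALSE negates it
atom_constraints <- function(ast, truth) {
  op <- ast[[1]]
  l <- lin_expr(ast[[2]])
  r <- lin_expr(ast[[3]])
  nm <- union(names(l$coef), names(r$coef))
  co <- stats::setNames(rep(0, length(nm)), nm)
  co[names(l$coef)] <- co[names(l$coef)] + l$coef
  co[names(r$coef)] <- co[names(r$coef)] - r$coef
  rhs <- r$const - l$const                      # lhs - rhs <= 0  => co.x <= rhs
  mk <- function(coef, rhs, strict) list(coef = coef, rhs = rhs, strict = strict)
  if (truth) {
    switch(op,
      "<"  = list(mk(co, rhs, TRUE)),
      "<=" = list(mk(co, rhs, FALSE)),
      ">"  = list(mk(-co, -rhs, TRUE)),
      ">=" = list(mk(-co, -rhs, FALSE)),
      "="  = list(mk(co, rhs, FALSE), mk(-co, -rhs, FALSE)),
      stop_fdt("unknown comparator"))
  } else {
    switch(op,                                   # negations
      "<"  = list(mk(-co, -rhs, FALSE)),
      "<=" = list(mk(-co, -rhs, TRUE)),
      ">"  = list(mk(co, rhs, FALSE)),
      ">=" = list(mk(co, rhs, TRUE)),
      "="  = "diseq",                            # handled by case split
      stop_fdt("unknown comparator"))
  }
}

## Fourier-Motzkin feasibility of constraints sum(coef*x) <=(strict?) rhs
## over the reals; returns a satisfying point when feasible.
fm_feasible <- function(cons) {
  vars <- unique(unlist(lapply(cons, function(c) names(c$coef))))
  elim <- list()
  cur <- cons
  for (v in vars) {
    has <- vapply(cur, function(c) !is.na(c$coef[v]) && c$coef[v] != 0, logical(1))
    with_v <- cur[has]
    cur <- cur[!has]
    elim[[v]] <- with_v
    ups <- Filter(function(c) c$coef[v] > 0, with_v)    # v <= ...
    los <- Filter(function(c) c$coef[v] < 0, with_v)    # v >= ...
    for (u in ups) for (l in los) {
      a <- u$coef[v]; b <- -l$coef[v]
      nm <- union(names(u$coef), names(l$coef))
      co <- stats::setNames(rep(0, length(nm)), nm)
      co[names(u$coef)] <- co[names(u$coef)] + u$coef / a
      co[names(l$coef)] <- co[names(l$coef)] + l$coef / b
      co <- co[names(co) != v]
      co <- co[co != 0]
      cur[[length(cur) + 1L]] <- list(
        coef = co,
        rhs = u$rhs / a + l$rhs / b,
        strict = u$strict || l$strict
      )
    }
  }
  # variable-free residue: 0 <= rhs (or 0 < rhs)
  for (c in cur) {
    ok <- if (c$strict) c$rhs > 0 else c$rhs >= 0
    if (!ok) return(list(feasible = FALSE, model = NULL))
  }
  # back-substitute a model
  model <- stats::setNames(numeric(0), character(0))
  for (v in rev(vars)) {
    lo <- -Inf; hi <- Inf; lo_strict <- FALSE; hi_strict <- FALSE
    for (c in elim[[v]]) {
      rest <- c$rhs
      for (u in names(c$coef)) {
        if (u == v) next
        rest <- rest - c$coef[u] * model[[u]]
      }
      bound <- rest / c$coef[v]
      if (c$coef[v] > 0) {                       # v <= bound
        if (bound < hi || (bound == hi && c$strict)) { hi <- bound; hi_strict <- c$strict }
      } else {                                   # v >= bound
        if (bound > lo || (bound == lo && c$strict)) { lo <- bound; lo_strict <- c$strict }
      }
    }
    val <- if (is.finite(lo) && is.finite(hi)) {
      if (!lo_strict && lo == hi) lo else (lo + hi) / 2
    } else if (is.finite(lo)) {
      if (lo_strict) lo + 1 else lo
    } else if (is.finite(hi)) {
      if (hi_strict) hi - 1 else hi
    } else 0
    model[[v]] <- val
  }
  list(feasible = TRUE, model = model)
}

## ---- DPLL over the Boolean abstraction ------------------------------------

BOOL_OPS <- c("and", "or", "not", "=>", "!", "true", "false")

ast_key <- function(ast) {
  if (is.character(ast)) return(ast)
  paste0("(", paste(vapply(ast, ast_key, character(1)), collapse = " "), ")")
}

is_arith_atom <- function(ast) {
  is.list(ast) && is.character(ast[[1]]) && ast[[1]] %in% CMP_OPS
}

collect_atoms <- function(ast, env) {
  if (is.character(ast)) {
    if (!ast %in% c("true", "false")) env$atoms[[ast]] <- list(kind = "bool", ast = ast)
    return(invisible())
  }
  if (is_arith_atom(ast)) {
    env$atoms[[ast_key(ast)]] <- list(kind = "arith", ast = ast)
    return(invisible())
  }
  for (a in ast[-1]) collect_atoms(a, env)
  invisible()
}

## three-valued evaluation under a partial atom assignment (NA = unknown)
eval3 <- function(ast, assign) {
  if (is.character(ast)) {
    if (ast == "true") return(TRUE)
    if (ast == "false") return(FALSE)
    return(assign[[ast]] %||% NA)
  }
  if (is_arith_atom(ast)) return(assign[[ast_key(ast)]] %||% NA)
  op <- ast[[1]]
  vals <- lapply(ast[-1], eval3, assign = assign)
  if (identical(op, "not")) {
    v <- vals[[1]]
    return(if (is.na(v)) NA else !v)
  }
  if (identical(op, "and")) {
    if (any(vapply(vals, isFALSE, logical(1)))) return(FALSE)
    if (any(vapply(vals, is.na, logical(1)))) return(NA)
    return(TRUE)
  }
  if (identical(op, "or")) {
    if (any(vapply(vals, isTRUE, logical(1)))) return(TRUE)
    if (any(vapply(vals, is.na, logical(1)))) return(NA)
    return(FALSE)
  }
  if (identical(op, "=>")) {
    a <- vals[[1]]; b <- vals[[2]]
    if (isFALSE(a) || isTRUE(b)) return(TRUE)
    if (is.na(a) || is.na(b)) return(NA)
    return(FALSE)
  }
  stop_fdt("unsupported Boolean operator: ", as.character(op))
}

## theory check of the arithmetic literals implied by `assign`
theory_check <- function(assign, atom_table) {
  cons <- list()
  diseqs <- list()
  for (key in names(assign)) {
    at <- atom_table[[key]]
    if (is.null(at) || at$kind != "arith" || is.na(assign[[key]])) next
    cc <- atom_constraints(at$ast, assign[[key]])
    if (identical(cc, "diseq")) {
      diseqs[[length(diseqs) + 1L]] <- at$ast
    } else {
      cons <- c(cons, cc)
    }
  }
  if (length(diseqs) == 0) return(fm_feasible(cons))
  # case-split each disequality a != b into a < b or a > b
  split <- function(i, acc) {
    if (i > length(diseqs)) return(fm_feasible(acc))
    for (branch in c("<", ">")) {
      lit <- atom_constraints(c(list(branch), diseqs[[i]][-1]), TRUE)
      res <- split(i + 1, c(acc, lit))
      if (res$feasible) return(res)
    }
    list(feasible = FALSE, model = NULL)
  }
  split(1, cons)
}

dpll <- function(assertions, atom_table, assign, deadline) {
  if (Sys.time() > deadline) stop(structure(
    class = c("fdt_smt_timeout", "error", "condition"),
    list(message = "solver timeout", call = NULL)))
  vals <- lapply(assertions, function(a) eval3(a$ast, assign))
  if (any(vapply(vals, isFALSE, logical(1)))) return(list(sat = FALSE))
  open <- which(vapply(vals, is.na, logical(1)))
  if (length(open) == 0) {
    th <- theory_check(assign, atom_table)
    if (!th$feasible) return(list(sat = FALSE))
    return(list(sat = TRUE, assign = assign, model = th$model))
  }
  # branch on the first unassigned atom of the first undecided assertion
  pick <- NULL
  pick_in <- function(ast) {
    if (!is.null(pick)) return(invisible())
    if (is.character(ast)) {
      if (!ast %in% c("true", "false") && is.na(assign[[ast]] %||% NA)) pick <<- ast
      return(invisible())
    }
    if (is_arith_atom(ast)) {
      k <- ast_key(ast)
      if (is.na(assign[[k]] %||% NA)) pick <<- k
      return(invisible())
    }
    for (a in ast[-1]) pick_in(a)
  }
  pick_in(assertions[[open[1]]]$ast)
  for (value in c(TRUE, FALSE)) {
    assign[[pick]] <- value
    res <- dpll(assertions, atom_table, assign, deadline)
    if (res$sat) return(res)
  }
  assign[[pick]] <- NULL
  list(sat = FALSE)
}

lra_check_assertions <- function(assertions, deadline) {
  env <- new.env()
  env$atoms <- list()
  for (a in assertions) collect_atoms(a$ast, env)
  dpll(assertions, env$atoms, list(), deadline)
}

#' Decide satisfiability of an SMT-LIB QF_LRA script
#'
#' Parses the script and decides the conjunction of its assertions. When
#' unsatisfiable, an unsat core over the named (tracked) assertions is
#' extracted: first every tracked assertion that is individually
#' inconsistent with the unnamed (fact) assertions, falling back to a
#' deletion-minimized core for genuinely conjoint conflicts. Unnamed
#' assertions are treated as background facts and never enter the core.
#'
#' @param text SMT-LIB 2 script (QF_LRA subset).
#' @param timeout Wall-clock budget in seconds; exceeding it yields
#'   status `"UNKNOWN"`.
#' @return List with `status` ("SAT"/"UNSAT"/"UNKNOWN"), `model` (named
#'   numeric/logical values for SAT), `core` (character ids for UNSAT),
#'   `solve_time` (seconds).
#' @export
smt_solve <- function(text, timeout = 1.0) {
  t0 <- Sys.time()
  deadline <- t0 + timeout
  parsed <- parse_smt_script(text)
  asserts <- parsed$assertions
  res <- tryCatch(
    lra_check_assertions(asserts, deadline),
    fdt_smt_timeout = function(e) NULL
  )
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  if (is.null(res)) {
    return(list(status = "UNKNOWN", model = NULL, core = NULL, solve_time = elapsed))
  }
  if (res$sat) {
    model <- res$model %||% stats::setNames(numeric(0), character(0))
    bools <- res$assign[vapply(res$assign, is.logical, logical(1))]
    return(list(status = "SAT",
                model = c(as.list(model), bools),
                core = NULL, solve_time = elapsed))
  }
  named_idx <- which(!vapply(asserts, function(a) is.null(a$name), logical(1)))
  facts <- asserts[setdiff(seq_along(asserts), named_idx)]
  core <- character(0)
  for (i in named_idx) {
    solo <- tryCatch(
      lra_check_assertions(c(facts, asserts[i]), deadline),
      fdt_smt_timeout = function(e) NULL
    )
    if (is.null(solo)) {
      return(list(status = "UNKNOWN", model = NULL, core = NULL,
                  solve_time = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
    if (!solo$sat) core <- c(core, asserts[[i]]$name)
  }
  if (length(core) == 0) {
    # conjoint conflict: deletion-based minimization over tracked assertions
    keep <- named_idx
    for (i in named_idx) {
      trial <- c(facts, asserts[setdiff(keep, i)])
      r <- lra_check_assertions(trial, deadline)
      if (!r$sat) keep <- setdiff(keep, i)
    }
    core <- vapply(asserts[keep], `[[`, "", "name")
  }
  list(status = "UNSAT", model = NULL, core = core,
       solve_time = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}
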