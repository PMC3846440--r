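# Kinetic-law math: MathML content markup <-> internal AST.
#
# AST node kinds (plain lists, field `k`):
#   num(v), id(name), time, const(name), op(op, args), piecewise(pieces,
#   otherwise), call(fn, args), lambda(vars, body)

MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
TIME_URLS <- c("http://www.sbml.org/sbml/symbols/time")

math_num <- function(v) list(k = "num", v = as.numeric(v))
math_id <- function(name) list(k = "id", name = as.character(name))
math_op <- function(op, ...) list(k = "op", op = op, args = list(...))

MATHML_OPS <- c("plus", "minus", "times", "divide", "power", "root", "exp",
                "ln", "log", "abs", "floor", "ceiling", "factorial",
                "sin", "cos", "tan", "sinh", "cosh", "tanh",
                "arcsin", "arccos", "arctan",
                "eq", "neq", "gt", "lt", "geq", "leq",
                "and", "or", "xor", "not", "delay")

MATHML_CONSTS <- c("pi", "exponentiale", "true", "false", "infinity",
                   "notanumber")

#' Parse a MathML content subtree into the internal math AST
#'
#' @param node an `xml2` node for the `<math>` element (or a single MathML
#'   content element).
#' @return a math AST (plain nested list).
#' @export
parse_mathml <- function(node) {
  kids <- xml2::xml_find_all(node, "./*")
  if (xml2::xml_name(node) == "math") {
    if (length(kids) != 1)
      stop_sbml("sbmlfuse_math_error", "<math> must contain exactly one child")
    return(parse_math_node(kids[[1]]))
  }
  parse_math_node(node)
}

parse_math_node <- function(node) {
  nm <- xml2::xml_name(node)
  switch(nm,
    cn = parse_cn(node),
    ci = math_id(trimws(xml2::xml_text(node))),
    csymbol = {
      url <- xml2::xml_attr(node, "definitionURL")
      if (!is.na(url) && grepl("/time$", url)) list(k = "time")
      else if (!is.na(url) && grepl("/delay$", url)) math_id("delay")
      else math_id(trimws(xml2::xml_text(node)))
    },
    apply = parse_apply(node),
    piecewise = parse_piecewise(node),
    lambda = parse_lambda(node),
    {
      if (nm %in% MATHML_CONSTS) list(k = "const", name = nm)
      else stop_sbml("sbmlfuse_math_error",
                     sprintf("unsupported MathML element <%s>", nm))
    })
}

parse_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (!is.na(type) && type %in% c("e-notation", "rational")) {
    # text nodes around <sep/>
    parts <- trimws(strsplit(xml2::xml_text(node), "\n")[[1]])
    txt <- xml2::xml_find_all(node, "./text()")
    vals <- as.numeric(trimws(vapply(txt, xml2::xml_text, character(1))))
    vals <- vals[!is.na(vals)]
    if (length(vals) != 2)
      stop_sbml("sbmlfuse_math_error", "malformed <cn> with <sep/>")
    if (type == "e-notation") return(math_num(vals[1] * 10^vals[2]))
    return(math_num(vals[1] / vals[2]))
  }
  v <- suppressWarnings(as.numeric(trimws(xml2::xml_text(node))))
  if (is.na(v))
    stop_sbml("sbmlfuse_math_error",
              sprintf("non-numeric <cn> content '%s'", xml2::xml_text(node)))
  math_num(v)
}

parse_apply <- function(node) {
  kids <- xml2::xml_find_all(node, "./*")
  if (!length(kids))
    stop_sbml("sbmlfuse_math_error", "empty <apply>")
  head <- kids[[1]]
  hname <- xml2::xml_name(head)
  rest <- kids[-1]
  if (hname == "ci")  # application of a (carried) function definition
    return(list(k = "call", fn = trimws(xml2::xml_text(head)),
                args = lapply(rest, parse_math_node)))
  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL")
    if (!is.na(url) && grepl("/delay$", url))
      return(list(k = "op", op = "delay", args = lapply(rest, parse_math_node)))
  }
  if (!hname %in% MATHML_OPS)
    stop_sbml("sbmlfuse_math_error",
              sprintf("unsupported MathML operator <%s>", hname))
  qual <- vapply(rest, xml2::xml_name, character(1))
  if (hname == "root") {
    deg <- math_num(2)
    argn <- rest
    if (length(qual) && qual[1] == "degree") {
      deg <- parse_math_node(xml2::xml_find_first(rest[[1]], "./*"))
      argn <- rest[-1]
    }
    return(list(k = "op", op = "root",
                args = c(list(deg), lapply(argn, parse_math_node))))
  }
  if (hname == "log") {
    base <- math_num(10)
    argn <- rest
    if (length(qual) && qual[1] == "logbase") {
      base <- parse_math_node(xml2::xml_find_first(rest[[1]], "./*"))
      argn <- rest[-1]
    }
    return(list(k = "op", op = "log",
                args = c(list(base), lapply(argn, parse_math_node))))
  }
  list(k = "op", op = hname, args = lapply(rest, parse_math_node))
}

parse_piecewise <- function(node) {
  pieces <- list()
  other <- NULL
  for (kid in xml2::xml_find_all(node, "./*")) {
    knm <- xml2::xml_name(kid)
    sub <- xml2::xml_find_all(kid, "./*")
    if (knm == "piece") {
      if (length(sub) != 2)
        stop_sbml("sbmlfuse_math_error", "<piece> needs value and condition")
      pieces[[length(pieces) + 1L]] <-
        list(val = parse_math_node(sub[[1]]), cond = parse_math_node(sub[[2]]))
    } else if (knm == "otherwise") {
      other <- parse_math_node(sub[[1]])
    } else stop_sbml("sbmlfuse_math_error",
                     sprintf("unexpected <%s> in <piecewise>", knm))
  }
  list(k = "piecewise", pieces = pieces, otherwise = other)
}

parse_lambda <- function(node) {
  vars <- character()
  body <- NULL
  for (kid in xml2::xml_find_all(node, "./*")) {
    if (xml2::xml_name(kid) == "bvar")
      vars <- c(vars, trimws(xml2::xml_text(kid)))
    else body <- parse_math_node(kid)
  }
  list(k = "lambda", vars = vars, body = body)
}

## ---- serialization ----

#' Serialize a math AST back to MathML content markup
#'
#' @param ast a math AST as produced by [parse_mathml()].
#' @param top emit the enclosing `<math>` element with its namespace.
#' @return character scalar of XML.
#' @export
write_mathml <- function(ast, top = TRUE) {
  body <- render_math_node(ast)
  if (top) sprintf("<math xmlns=\"%s\">%s</math>", MATHML_NS, body) else body
}

render_math_node <- function(n) {
  switch(n$k,
    num = {
      v <- n$v
      if (!is.na(v) && is.finite(v) && v == trunc(v) && abs(v) < 2^31)
        sprintf("<cn type=\"integer\">%s</cn>", format(as.integer(v)))
      else sprintf("<cn>%s</cn>", fmt_num(v))
    },
    id = sprintf("<ci> %s </ci>", n$name),
    time = sprintf(
      "<csymbol encoding=\"text\" definitionURL=\"%s\"> time </csymbol>",
      TIME_URLS[1]),
    const = sprintf("<%s/>", n$name),
    op = {
      args <- n$args
      if (n$op == "root")
        sprintf("<apply><root/><degree>%s</degree>%s</apply>",
                render_math_node(args[[1]]),
                paste(vapply(args[-1], render_math_node, character(1)),
                      collapse = ""))
      else if (n$op == "log")
        sprintf("<apply><log/><logbase>%s</logbase>%s</apply>",
                render_math_node(args[[1]]),
                paste(vapply(args[-1], render_math_node, character(1)),
                      collapse = ""))
      else sprintf("<apply><%s/>%s</apply>", n$op,
                   paste(vapply(args, render_math_node, character(1)),
                         collapse = ""))
    },
    piecewise = {
      ps <- vapply(n$pieces, function(p)
        sprintf("<piece>%s%s</piece>", render_math_node(p$val),
                render_math_node(p$cond)), character(1))
      oth <- if (!is.null(n$otherwise))
        sprintf("<otherwise>%s</otherwise>", render_math_node(n$otherwise))
      else ""
      sprintf("<piecewise>%s%s</piecewise>", paste(ps, collapse = ""), oth)
    },
    call = sprintf("<apply><ci> %s </ci>%s</apply>", n$fn,
                   paste(vapply(n$args, render_math_node, character(1)),
                         collapse = "")),
    lambda = sprintf("<lambda>%s%s</lambda>",
                     paste(sprintf("<bvar><ci> %s </ci></bvar>", n$vars),
                           collapse = ""),
                     render_math_node(n$body)),
    stop_sbml("sbmlfuse_math_error", sprintf("unknown AST kind '%s'", n$k)))
}

## ---- evaluation ----

#' Evaluate a math AST against an identifier environment
#'
#' Reference interpreter for kinetic-law math: arithmetic per node kind,
#' piecewise resolved by the first true branch, function applications
#' resolved against `fundefs` (named list of lambda ASTs). Division by zero
#' and unresolved identifiers are errors carrying the expression path.
#'
#' @param expr math AST.
#' @param env named list / environment mapping identifiers (and implicitly
#'   `time`) to numbers.
#' @param fundefs named list of lambda ASTs for function applications.
#' @param time value bound to the MathML time symbol.
#' @return numeric scalar.
#' @export
eval_math <- function(expr, env = list(), fundefs = list(), time = 0) {
  eval_node(expr, env, fundefs, time, path = "/")
}

lookup_id <- function(name, env, path) {
  v <- if (is.environment(env)) {
    if (exists(name, envir = env, inherits = FALSE))
      get(name, envir = env) else NULL
  } else env[[name]]
  if (is.null(v))
    stop_sbml("sbmlfuse_math_error",
              sprintf("unresolved identifier '%s' at %s", name, path))
  as.numeric(v)
}

eval_node <- function(n, env, fundefs, time, path) {
  switch(n$k,
    num = n$v,
    id = lookup_id(n$name, env, path),
    time = time,
    const = switch(n$name, pi = pi, exponentiale = exp(1), true = 1,
                   false = 0, infinity = Inf, notanumber = NaN),
    op = eval_op(n, env, fundefs, time, path),
    piecewise = {
      for (i in seq_along(n$pieces)) {
        p <- n$pieces[[i]]
        if (eval_node(p$cond, env, fundefs, time,
                      paste0(path, "piecewise/cond", i)) != 0)
          return(eval_node(p$val, env, fundefs, time,
                           paste0(path, "piecewise/val", i)))
      }
      if (is.null(n$otherwise)) return(NaN)
      eval_node(n$otherwise, env, fundefs, time,
                paste0(path, "piecewise/otherwise"))
    },
    call = {
      fd <- fundefs[[n$fn]]
      if (is.null(fd))
        stop_sbml("sbmlfuse_math_error",
                  sprintf("unknown function '%s' at %s", n$fn, path))
      argv <- lapply(seq_along(n$args), function(i)
        eval_node(n$args[[i]], env, fundefs, time,
                  paste0(path, n$fn, "/arg", i)))
      names(argv) <- fd$vars[seq_along(argv)]
      inner <- if (is.environment(env)) as.list(env) else env
      eval_node(fd$body, utils::modifyList(inner, argv), fundefs, time,
                paste0(path, n$fn, "/body"))
    },
    stop_sbml("sbmlfuse_math_error", sprintf("cannot evaluate '%s'", n$k)))
}

eval_op <- function(n, env, fundefs, time, path) {
  a <- lapply(seq_along(n$args), function(i)
    eval_node(n$args[[i]], env, fundefs, time,
              paste0(path, n$op, "/", i)))
  a <- unlist(a)
  switch(n$op,
    plus = sum(a),
    minus = if (length(a) == 1) -a else a[1] - a[2],
    times = prod(a),
    divide = {
      if (a[2] == 0)
        stop_sbml("sbmlfuse_math_error",
                  sprintf("division by zero at %s%s", path, n$op))
      a[1] / a[2]
    },
    power = a[1]^a[2],
    root = a[2]^(1 / a[1]),
    exp = exp(a), ln = log(a),
    log = log(a[2], base = a[1]),
    abs = abs(a), floor = floor(a), ceiling = ceiling(a),
    factorial = factorial(a),
    sin = sin(a), cos = cos(a), tan = tan(a),
    sinh = sinh(a), cosh = cosh(a), tanh = tanh(a),
    arcsin = asin(a), arccos = acos(a), arctan = atan(a),
    eq = as.numeric(a[1] == a[2]), neq = as.numeric(a[1] != a[2]),
    gt = as.numeric(a[1] > a[2]), lt = as.numeric(a[1] < a[2]),
    geq = as.numeric(a[1] >= a[2]), leq = as.numeric(a[1] <= a[2]),
    and = as.numeric(all(a != 0)), or = as.numeric(any(a != 0)),
    xor = as.numeric(sum(a != 0) %% 2 == 1),
    not = as.numeric(a == 0),
    delay = stop_sbml("sbmlfuse_unsupported_error",
                      "delay terms are unsupported for simulation"),
    stop_sbml("sbmlfuse_math_error", sprintf("unknown operator '%s'", n$op)))
}

## ---- compilation to R expressions (fast path for the ODE engine) ----

fold_call <- function(op, args, empty) {
  if (!length(args)) return(empty)
  Reduce(function(x, y) call(op, x, y), args)
}

math_to_rexpr <- function(n, fundefs = list(), depth = 0L) {
  if (depth > 50L)
    stop_sbml("sbmlfuse_math_error", "function definitions nested too deeply")
  rec <- function(x) math_to_rexpr(x, fundefs, depth)
  switch(n$k,
    num = n$v,
    id = as.name(n$name),
    time = as.name(".time_"),
    const = switch(n$name, pi = pi, exponentiale = exp(1), true = TRUE,
                   false = FALSE, infinity = Inf, notanumber = NaN),
    op = {
      a <- lapply(n$args, rec)
      switch(n$op,
        plus = fold_call("+", a, 0),
        minus = if (length(a) == 1) call("-", a[[1]]) else call("-", a[[1]], a[[2]]),
        times = fold_call("*", a, 1),
        divide = call("/", a[[1]], a[[2]]),
        power = call("^", a[[1]], a[[2]]),
        root = call("^", a[[2]], call("/", 1, a[[1]])),
        exp = call("exp", a[[1]]), ln = call("log", a[[1]]),
        log = call("log", a[[2]], a[[1]]),
        abs = call("abs", a[[1]]), floor = call("floor", a[[1]]),
        ceiling = call("ceiling", a[[1]]), factorial = call("factorial", a[[1]]),
        sin = call("sin", a[[1]]), cos = call("cos", a[[1]]),
        tan = call("tan", a[[1]]),
        sinh = call("sinh", a[[1]]), cosh = call("cosh", a[[1]]),
        tanh = call("tanh", a[[1]]),
        arcsin = call("asin", a[[1]]), arccos = call("acos", a[[1]]),
        arctan = call("atan", a[[1]]),
        eq = call("==", a[[1]], a[[2]]), neq = call("!=", a[[1]], a[[2]]),
        gt = call(">", a[[1]], a[[2]]), lt = call("<", a[[1]], a[[2]]),
        geq = call(">=", a[[1]], a[[2]]), leq = call("<=", a[[1]], a[[2]]),
        and = fold_call("&&", a, TRUE), or = fold_call("||", a, FALSE),
        xor = call("xor", a[[1]], a[[2]]), not = call("!", a[[1]]),
        delay = stop_sbml("sbmlfuse_unsupported_error",
                          "delay terms are unsupported for simulation"),
        stop_sbml("sbmlfuse_math_error",
                  sprintf("unknown operator '%s'", n$op)))
    },
    piecewise = {
      out <- if (is.null(n$otherwise)) NaN else rec(n$otherwise)
      for (p in rev(n$pieces))
        out <- call("if", rec(p$cond), rec(p$val), out)
      out
    },
    call = {
      fd <- fundefs[[n$fn]]
      if (is.null(fd))
        stop_sbml("sbmlfuse_math_error",
                  sprintf("unknown function '%s'", n$fn))
      sub <- stats::setNames(lapply(n$args, rec), fd$vars[seq_along(n$args)])
      eval(call("substitute", math_to_rexpr(fd$body, fundefs, depth + 1L),
                sub))
    },
    stop_sbml("sbmlfuse_math_error", sprintf("unknown AST kind '%s'", n$k)))
}

## ---- AST utilities ----

# identifier leaves (excluding lambda bound variables); includes called
# function names when `include_calls`
math_identifiers <- function(n, include_calls = TRUE) {
  switch(n$k,
    num = , time = , const = character(),
    id = n$name,
    op = unique(unlist(lapply(n$args, math_identifiers, include_calls))),
    piecewise = {
      ids <- unlist(lapply(n$pieces, function(p)
        c(math_identifiers(p$val, include_calls),
          math_identifiers(p$cond, include_calls))))
      if (!is.null(n$otherwise))
        ids <- c(ids, math_identifiers(n$otherwise, include_calls))
      unique(ids)
    },
    call = unique(c(if (include_calls) n$fn,
                    unlist(lapply(n$args, math_identifiers, include_calls)))),
    lambda = setdiff(math_identifiers(n$body, include_calls), n$vars),
    character())
}

# rename identifier leaves (and called function names) through `map`,
# skipping names listed in `shadow` (e.g. local parameters)
rename_math_ids <- function(n, map, shadow = character()) {
  rn <- function(x) rename_math_ids(x, map, shadow)
  switch(n$k,
    id = {
      if (!n$name %in% shadow && !is.null(map[[n$name]]))
        n$name <- map[[n$name]]
      n
    },
    op = { n$args <- lapply(n$args, rn); n },
    piecewise = {
      n$pieces <- lapply(n$pieces, function(p)
        list(val = rn(p$val), cond = rn(p$cond)))
      if (!is.null(n$otherwise)) n$otherwise <- rn(n$otherwise)
      n
    },
    call = {
      if (!is.null(map[[n$fn]])) n$fn <- map[[n$fn]]
      n$args <- lapply(n$args, rn)
      n
    },
    lambda = {
      n$body <- rename_math_ids(n$body, map, union(shadow, n$vars))
      n
    },
    n)
}

# compact infix rendering, used in warning messages
math_to_string <- function(n) {
  switch(n$k,
    num = fmt_num(n$v),
    id = n$name,
    time = "time",
    const = n$name,
    op = {
      a <- vapply(n$args, math_to_string, character(1))
      sym <- c(plus = " + ", minus = " - ", times = " * ", divide = " / ",
               power = "^")[n$op]
      if (!is.na(sym)) {
        if (n$op == "minus" && length(a) == 1) paste0("-", a)
        else paste0("(", paste(a, collapse = sym), ")")
      } else paste0(n$op, "(", paste(a, collapse = ", "), ")")
    },
    piecewise = "piecewise(...)",
    call = paste0(n$fn, "(",
                  paste(vapply(n$args, math_to_string, character(1)),
                        collapse = ", "), ")"),
    lambda = "lambda(...)",
    "?")
}
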