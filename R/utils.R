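`%||%` <- function(a, b) if (is.null(a)) b else a

# shortest decimal form that survives as.numeric() round-trip
fmt_num <- function(x) {
  if (is.na(x)) return(NA_character_)
  if (x == trunc(x) && abs(x) < 2^31) return(format(as.integer(x)))
  for (d in 1:17) {
    s <- sprintf("%.*g", d, x)
    if (as.numeric(s) == x) return(s)
  }
  sprintf("%.17g", x)
}

xml_escape_attr <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

xml_escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  gsub("<", "&lt;", x, fixed = TRUE)
}

# evaluate expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_sbml <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sbmlfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_true_attr <- function(x, default = FALSE) {
  if (is.na(x)) return(default)
  identical(x, "true") || identical(x, "1")
}

bool_attr <- function(x) if (isTRUE(x)) "true" else "false"
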