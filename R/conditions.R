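#' @keywords internal
#' Rule-condition expression language
#'
#' Clause conditions are written as R comparison/logic expressions over node
#' names, e.g. `"Cln1_2 >= 2 & !(Whi5 >= 2)"`. Only comparisons, boolean
#' operators, parentheses, node names, integer literals and the literals
#' TRUE/FALSE are admitted, so conditions serialize unchanged into the native
#' text format and evaluate vectorized over ensembles of states.
#' @name conditions
NULL

.cond_allowed_ops <- c("&", "|", "!", "(", ">=", "<=", "==", ">", "<", "!=",
                       "&&", "||")

cond_parse <- function(text) {
  ex <- tryCatch(
    parse(text = text, keep.source = FALSE),
    error = function(e) stop("malformed condition `", text, "`: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ex) != 1L) {
    stop("condition `", text, "` must be a single expression", call. = FALSE)
  }
  ex[[1L]]
}

cond_check <- function(expr, text = deparse(expr)) {
  walk <- function(e) {
    if (is.symbol(e) || is.numeric(e) || is.logical(e)) return(invisible())
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      if (!op %in% .cond_allowed_ops) {
        stop("condition `", text, "` uses disallowed operator or function `",
             op, "`", call. = FALSE)
      }
      for (i in seq_along(e)[-1L]) walk(e[[i]])
      return(invisible())
    }
    stop("condition `", text, "` contains an unsupported element", call. = FALSE)
  }
  walk(expr)
  invisible(expr)
}

cond_vars <- function(expr) all.vars(expr)

#' @keywords internal
cond_eval <- function(expr, env, n) {
  v <- eval(expr, envir = env)
  if (length(v) != n) v <- rep_len(v, n)
  v & !is.na(v)
}
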