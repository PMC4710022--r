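#' Right-continuous step functions
#'
#' All estimated processes in the package (counting processes, risk sets,
#' censoring survival, hazards, incidence curves) are piecewise-constant in
#' time and are represented as `tp_step` objects: a strictly increasing grid
#' of jump times, the value held from each jump onward, and the value before
#' the first jump.
#'
#' Two evaluation conventions coexist in survival analysis and both are
#' needed here. Counting processes and product-limit estimators are cadlag:
#' the value *at* a jump time includes the jump (`side = "right"`). Risk-set
#' processes such as \eqn{\hat Y(t) = \sum_i \xi_i I(X_i \ge t)/\pi_i} are
#' left-continuous: a subject exiting at `t` is still at risk at `t`, so the
#' stored values are the post-exit levels and evaluation *at* `t` returns the
#' value of the last jump strictly before `t` (`side = "left"`). Each object
#' carries its own default side, set at construction.
#'
#' @param time Strictly increasing numeric vector of jump times (all >= 0).
#' @param value Numeric vector, same length as `time`; `value[j]` is the
#'   level held on `[time[j], time[j+1])` (right side) or
#'   `(time[j], time[j+1]]` (left side).
#' @param v0 Value before the first jump (at "0-").
#' @param side Default evaluation convention, `"right"` (cadlag) or `"left"`.
#' @return `step_function()` returns a `tp_step` object; `step_eval()` a
#'   numeric vector the length of `t`.
#' @examples
#' f <- step_function(c(1, 3), c(0.5, 0.25), v0 = 1)
#' step_eval(f, c(0, 1, 2, 3, 4))
#' step_eval(f, 3, side = "left") # left limit at 3
#' @export
step_function <- function(time, value, v0 = 0, side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(is.numeric(time), is.numeric(value), length(time) == length(value))
  if (length(time) && (any(diff(time) <= 0) || any(time < 0) || anyNA(time))) {
    stop("`time` must be strictly increasing and nonnegative", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), value = as.numeric(value), v0 = as.numeric(v0)),
    side = side, class = "tp_step"
  )
}

#' @rdname step_function
#' @param f A `tp_step` object.
#' @param t Numeric vector of evaluation times.
#' @export
step_eval <- function(f, t, side = NULL) {
  stopifnot(inherits(f, "tp_step"))
  side <- side %||% attr(f, "side")
  side <- match.arg(side, c("right", "left"))
  idx <- findInterval(t, f$time, left.open = identical(side, "left"))
  c(f$v0, f$value)[idx + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tp_step <- function(x, ...) {
  cat("<tp_step> ", length(x$time), " jumps, side = ", attr(x, "side"),
    ", v0 = ", format(x$v0), "\n",
    sep = ""
  )
  print(utils::head(tibble(time = x$time, value = x$value), 10))
  invisible(x)
}

#' @method as_tibble tp_step
#' @export
as_tibble.tp_step <- function(x, ...) {
  tibble(time = x$time, value = x$value)
}
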