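#' Measured value with standard uncertainty
#'
#' Lightweight value-with-uncertainty vector used by the recovery and
#' mass-balance arithmetic. Sums and differences combine uncertainties in
#' quadrature; products and ratios combine relative uncertainties in
#' quadrature (first-order GUM propagation, inputs assumed uncorrelated).
#'
#' @param value Numeric vector of central values.
#' @param u Numeric vector of standard uncertainties (>= 0), recycled.
#' @return Object of class `meas`.
#' @examples
#' meas(1.637, 0.131) / meas(1.712, 0.014)  # ratio with propagated u
#' @export
meas <- function(value, u = 0) {
  if (any(u < 0)) stop("uncertainties must be >= 0")
  n <- max(length(value), length(u))
  structure(list(value = rep_len(as.numeric(value), n),
                 u = rep_len(as.numeric(u), n)),
            class = "meas")
}

#' @rdname meas
#' @param x Object to convert or query.
#' @export
as_meas <- function(x) {
  if (inherits(x, "meas")) x else meas(x, 0)
}

#' @rdname meas
#' @export
meas_value <- function(x) as_meas(x)$value

#' @rdname meas
#' @export
meas_u <- function(x) as_meas(x)$u

#' @export
format.meas <- function(x, digits = 4, ...) {
  sprintf("%s ± %s", signif(x$value, digits), signif(x$u, digits))
}

#' @export
print.meas <- function(x, ...) {
  cat("<meas>", format(x), "\n")
  invisible(x)
}

#' @export
length.meas <- function(x) length(x$value)

#' @export
Ops.meas <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") return(meas(-meas_value(e1), meas_u(e1)))
    if (.Generic == "+") return(e1)
    stop("unary '", .Generic, "' not defined for meas")
  }
  a <- as_meas(e1); b <- as_meas(e2)
  switch(.Generic,
    "+" = meas(a$value + b$value, sqrt(a$u^2 + b$u^2)),
    "-" = meas(a$value - b$value, sqrt(a$u^2 + b$u^2)),
    "*" = {
      v <- a$value * b$value
      meas(v, abs(v) * sqrt(.rel_u(a)^2 + .rel_u(b)^2))
    },
    "/" = {
      v <- a$value / b$value
      meas(v, abs(v) * sqrt(.rel_u(a)^2 + .rel_u(b)^2))
    },
    stop("'", .Generic, "' not defined for meas objects")
  )
}

# Relative uncertainty; 0 when the value is 0 and u is 0.
.rel_u <- function(x) ifelse(x$value == 0 & x$u == 0, 0, x$u / x$value)
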