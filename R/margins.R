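#' Per-direction setup margins in mm
#'
#' Six non-negative mm margins in the fixed patient frame, ordered
#' (left, right, anterior, posterior, superior, inferior). The institutional
#' clinical margin set is 5 mm in every direction except 3 mm posteriorly,
#' available as [clinical_margin_set()].
#'
#' @param left,right,anterior,posterior,superior,inferior mm margins (>= 0).
#' @return A named numeric vector of class `margin_set`.
#' @export
margin_set <- function(left, right = left, anterior = left, posterior = anterior,
                       superior = left, inferior = superior) {
  m <- c(left = left, right = right, anterior = anterior,
         posterior = posterior, superior = superior, inferior = inferior)
  if (any(!is.finite(m)) || any(m < 0)) stop("margins must be finite and >= 0")
  structure(as.numeric(m),
            names = names(m),
            class = "margin_set")
}

as_margin_set <- function(x, allow_zero = TRUE) {
  if (inherits(x, "margin_set")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6L) stop("a margin set needs 6 components")
  do.call(margin_set, as.list(setNames(x, c("left", "right", "anterior",
                                            "posterior", "superior", "inferior"))))
}

#' @export
print.margin_set <- function(x, ...) {
  cat(sprintf("margins (mm): L %.1f  R %.1f  A %.1f  P %.1f  S %.1f  I %.1f\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

#' The institutional clinical margin set: 5 mm everywhere, 3 mm posterior
#' @return A [margin_set()].
#' @export
clinical_margin_set <- function() {
  margin_set(left = 5, right = 5, anterior = 5, posterior = 3,
             superior = 5, inferior = 5)
}

mean_margin <- function(m) mean(as.numeric(m))

#' Clamp a margin to physical bounds
#'
#' Margins below `lower` are raised to it (irreducible setup uncertainty from
#' the coincidence of radiation and mechanical isocenters, default 1.5 mm);
#' margins above `upper` are capped (clinical guideline, default 5.0 mm).
#' Idempotent and monotone; vectorized.
#'
#' @param value mm value(s).
#' @param lower,upper bounds with `0 < lower <= upper`.
#' @return clamped mm value(s).
#' @export
clamp_margin <- function(value, lower = 1.5, upper = 5.0) {
  if (!is.finite(lower) || !is.finite(upper) || lower <= 0 || lower > upper) {
    stop("invalid bounds: need 0 < lower <= upper")
  }
  pmin(pmax(value, lower), upper)
}
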