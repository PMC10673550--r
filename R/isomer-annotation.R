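#' Retention-index calibrant ladder
#'
#' An ordered set of calibrants mapping retention time (minutes) to
#' retention index. Both columns must be strictly increasing; at least two
#' calibrants are required.
#'
#' @param rt numeric vector of calibrant retention times (min).
#' @param ri numeric vector of calibrant retention indices.
#' @return An `ri_ladder` object.
#' @export
ri_ladder <- function(rt, ri) {
  stopifnot(length(rt) == length(ri), length(rt) >= 2)
  if (any(diff(rt) <= 0) || any(diff(ri) <= 0)) {
    stop("ladder must be strictly increasing in both rt and ri")
  }
  structure(list(rt = as.numeric(rt), ri = as.numeric(ri)),
            class = "ri_ladder")
}

#' Default synthetic RI ladder
#'
#' Nine calibrants spanning RI 2000-3600 over the 2-36 min window of the
#' 38 min gradient, with a mildly convex rt-ri relationship.
#' @export
default_ri_ladder <- function() {
  ri <- seq(2000, 3600, by = 200)
  ri_ladder(rt = 2 + 34 * ((ri - 2000) / 1600) ^ 1.1, ri = ri)
}

#' Convert retention time to retention index
#'
#' Piecewise-linear interpolation between ladder calibrants (a Kovats-style
#' scheme; the original calibration method of the emulating study is not
#' public, so this interpolation rule is a documented design choice).
#' Retention times outside the ladder are linearly extrapolated from the
#' terminal segment and flagged.
#'
#' @param rt numeric vector of retention times (min).
#' @param ladder an [ri_ladder()].
#' @return Numeric RI vector with a logical attribute `"extrapolated"`.
#' @export
rt_to_ri <- function(rt, ladder) {
  stopifnot(inherits(ladder, "ri_ladder"))
  ri <- .piecewise_linear(rt, ladder$rt, ladder$ri)
  extrap <- rt < ladder$rt[1] | rt > ladder$rt[length(ladder$rt)]
  if (any(extrap)) {
    warning(sum(extrap), " retention time(s) outside the ladder; extrapolated")
  }
  attr(ri, "extrapolated") <- extrap
  ri
}

#' Convert retention index to retention time (ladder inverse)
#' @inheritParams rt_to_ri
#' @param ri numeric vector of retention indices.
#' @export
ri_to_rt <- function(ri, ladder) {
  stopifnot(inherits(ladder, "ri_ladder"))
  .piecewise_linear(ri, ladder$ri, ladder$rt)
}

# Piecewise-linear interpolation with terminal-segment extrapolation.
.piecewise_linear <- function(x, knots_x, knots_y) {
  n <- length(knots_x)
  idx <- findInterval(x, knots_x, all.inside = TRUE)
  x0 <- knots_x[idx]; x1 <- knots_x[idx + 1]
  y0 <- knots_y[idx]; y1 <- knots_y[idx + 1]
  y0 + (x - x0) * (y1 - y0) / (x1 - x0)
}

#' Fit a log10(RI) vs ester-bond position calibration line
#'
#' Ordinary least squares of `y = log10(ri)` on `x = position` over authentic
#' standards of one family. Within a family, later ester-bond positions
#' elute earlier, so the fitted slope is negative.
#'
#' @param standards data.frame with columns `position` and `ri` (>= 3 rows,
#'   >= 3 distinct positions).
#' @param family family name attached to the curve.
#' @return A `position_curve` object: `intercept` (a), `slope` (b), `r2`,
#'   `residuals`, `support`, `family`.
#' @examples
#' std <- data.frame(position = c(13, 12, 10, 9, 5),
#'                   ri = 10 ^ (3.50 - 0.0036 * c(13, 12, 10, 9, 5)))
#' fit_position_curve(std, "OAHSA") # intercept 3.50, slope -0.0036, r2 = 1
#' @export
fit_position_curve <- function(standards, family = "") {
  stopifnot(is.data.frame(standards),
            all(c("position", "ri") %in% names(standards)))
  if (nrow(standards) < 3) stop("need >= 3 standards to fit a position curve")
  if (length(unique(standards$position)) < 3) {
    stop("standards must cover >= 3 distinct positions")
  }
  fit <- stats::lm(log10(ri) ~ position, data = standards)
  y <- log10(standards$ri)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(
      family = family,
      intercept = unname(stats::coef(fit)[1]),
      slope = unname(stats::coef(fit)[2]),
      r2 = r2,
      residuals = unname(stats::residuals(fit)),
      support = standards[, c("position", "ri")]
    ),
    class = "position_curve"
  )
}

#' @export
print.position_curve <- function(x, ...) {
  cat(sprintf("Position curve [%s]: log10(RI) = %.4f %+.6f * position (r2 = %.4f, n = %d)\n",
              x$family, x$intercept, x$slope, x$r2, nrow(x$support)))
  invisible(x)
}

#' Predict an ester-bond position from a retention index
#'
#' Inverts the fitted calibration line: `x_hat = (log10(ri) - a) / b`,
#' rounds to the nearest integer position, and reports the rounding residual
#' as a confidence measure (0 = on-grid). Residuals above `low_conf`
#' positions are flagged `LOW_CONFIDENCE` but still reported. Positions
#' outside `[2, max_position]` are rejected.
#'
#' @param curve a [fit_position_curve()] result (or a list with `intercept`
#'   and `slope`, e.g. a published calibration).
#' @param ri retention index of the query (scalar, > 0).
#' @param max_position upper bound of valid positions
#'   (`hfa carbons - 1`); `NA` skips the upper check.
#' @param low_conf confidence threshold in position units (default 0.35).
#' @return A list: `position`, `confidence`, `x_hat`, `low_confidence`,
#'   `method = "RI_REGRESSION"`.
#' @examples
#' curve <- list(intercept = 3.50, slope = -0.0036)
#' predict_position(curve, 10 ^ (3.50 - 0.0036 * 11))$position # 11
#' @export
predict_position <- function(curve, ri, max_position = NA, low_conf = 0.35) {
  stopifnot(length(ri) == 1, ri > 0)
  if (curve$slope == 0) stop("curve slope is zero; position is undetermined")
  x_hat <- (log10(ri) - curve$intercept) / curve$slope
  position <- as.integer(round(x_hat))
  if (position < 2 || (!is.na(max_position) && position > max_position)) {
    stop(sprintf("predicted position %d outside valid range [2, %s]",
                 position, ifelse(is.na(max_position), "?", max_position)))
  }
  confidence <- abs(x_hat - position)
  list(position = position, confidence = confidence, x_hat = x_hat,
       low_confidence = confidence > low_conf, method = "RI_REGRESSION")
}

#' Match a peak pair to an authentic standard by retention time
#'
#' Same-family standards within `rt_match_tol` minutes are candidates; the
#' smallest |delta RT| wins. Two candidates at exactly equal |delta RT| are
#' ambiguous and raise an error rather than a silent guess. No candidate
#' returns `NULL` (the caller falls back to RI regression).
#'
#' @param family family of the query pair.
#' @param rt retention time of the query pair (min).
#' @param standards data.frame with `family`, `position`, `rt`.
#' @param rt_match_tol match tolerance in minutes (default 0.05).
#' @return `NULL`, or a list: `position`, `delta_rt`,
#'   `method = "STANDARD_MATCH"`.
#' @export
match_standard <- function(family, rt, standards, rt_match_tol = 0.05) {
  stopifnot(all(c("family", "position", "rt") %in% names(standards)))
  cand <- standards[standards$family == family &
                      abs(standards$rt - rt) <= rt_match_tol, ]
  if (nrow(cand) == 0) return(NULL)
  d <- abs(cand$rt - rt)
  best <- which(d == min(d))
  if (length(best) > 1) {
    stop("ambiguous standard match: ", paste(cand$position[best], collapse = ", "))
  }
  list(position = cand$position[best], delta_rt = cand$rt[best] - rt,
       method = "STANDARD_MATCH")
}

#' Annotate peak pairs with ester-bond positions
#'
#' For each family-assigned pair: try a retention match against authentic
#' standards first; otherwise, if the family has >= 3 standards, fall back
#' to the fitted log10(RI)-vs-position regression. Pairs in families without
#' a usable curve stay unannotated.
#'
#' @param pairs data.frame of family-assigned pairs (needs `family`, `rt`).
#' @param standards standards table ([fahfa_standards()] layout).
#' @param ladder an [ri_ladder()] for RT -> RI conversion.
#' @param rt_match_tol standard-match tolerance (min).
#' @param max_positions named vector family -> maximum valid position; `NA`
#'   entries skip the range check.
#' @return `pairs` with added columns `method`, `position`, `confidence`,
#'   `low_confidence`.
#' @export
annotate_pairs <- function(pairs, standards, ladder = default_ri_ladder(),
                           rt_match_tol = 0.05, max_positions = NULL) {
  curves <- list()
  for (fam in unique(standards$family)) {
    s <- standards[standards$family == fam, ]
    if (nrow(s) >= 3 && length(unique(s$position)) >= 3) {
      curves[[fam]] <- fit_position_curve(
        data.frame(position = s$position, ri = s$ri), fam)
    }
  }
  n <- nrow(pairs)
  pairs$method <- rep(NA_character_, n)
  pairs$position <- rep(NA_integer_, n)
  pairs$confidence <- rep(NA_real_, n)
  pairs$low_confidence <- rep(NA, n)
  for (i in seq_len(n)) {
    fam <- pairs$family[i]
    if (is.na(fam) || fam == "UNASSIGNED") next
    m <- match_standard(fam, pairs$rt[i], standards, rt_match_tol)
    if (is.null(m) && !is.null(curves[[fam]])) {
      ri <- suppressWarnings(rt_to_ri(pairs$rt[i], ladder))
      maxp <- if (!is.null(max_positions)) max_positions[[fam]] else NA
      m <- tryCatch(predict_position(curves[[fam]], ri, max_position = maxp),
                    error = function(e) NULL)
    }
    if (!is.null(m)) {
      pairs$method[i] <- m$method
      pairs$position[i] <- m$position
      pairs$confidence[i] <- if (is.null(m$confidence)) 0 else m$confidence
      pairs$low_confidence[i] <- isTRUE(m$low_confidence)
    }
  }
  pairs
}
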