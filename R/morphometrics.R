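# The two auxiliary pelvimetric distances.

#' Distance between the outer boundaries of the pubic tubercles
#'
#' Euclidean distance between the tubercle apex and its contralateral
#' counterpart (which lies on the opposite hemipelvis and is therefore the
#' one landmark exempt from the on-surface check).
#'
#' @param ls a [landmark_set()] with `contralateral_tubercle_apex`.
#' @return distance in mm.
#' @export
intertubercular_distance <- function(ls) {
  if (is.null(ls$contralateral_tubercle_apex)) {
    stop("missing-landmark error: contralateral_tubercle_apex is required",
         call. = FALSE)
  }
  vnorm(as.numeric(ls$tubercle_apex) -
          as.numeric(ls$contralateral_tubercle_apex))
}

#' Vertical extent of the pubic symphysis
#'
#' Distance between the upper and lower symphysis boundary landmarks.  By
#' default the straight Euclidean distance; `method = "projected"` projects
#' the two points onto the upper-to-lower symphysis axis first (identical
#' for exactly collinear landmarks, exposed because no body axis is part of
#' the landmark model).
#'
#' @param ls a [landmark_set()].
#' @param method `"straight"` or `"projected"`.
#' @return distance in mm; 0 with a warning for coincident landmarks.
#' @export
symphysis_vertical_distance <- function(ls, method = c("straight", "projected")) {
  method <- match.arg(method)
  up <- as.numeric(ls$symphysis_upper)
  lo <- as.numeric(ls$symphysis_lower)
  if (is.null(up) || is.null(lo)) {
    stop("missing-landmark error: symphysis_upper/symphysis_lower required",
         call. = FALSE)
  }
  d <- vnorm(up - lo)
  if (d < 1e-9) {
    warning("degenerate-landmark warning: symphysis boundary points coincide")
    return(0)
  }
  if (method == "projected") {
    ax <- unitv(up - lo)
    d <- abs(sum((up - lo) * ax))
  }
  d
}
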