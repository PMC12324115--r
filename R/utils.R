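#' Median and quartiles with a fixed, documented convention
#'
#' Day counts are small integers, so the interpolation scheme matters.  The
#' package uses one convention everywhere: the quantile at probability `p`
#' of a sorted sample `x[1] <= ... <= x[n]` is `x[ceiling(n * p)]` when
#' `n * p` is not an integer, and the mean of `x[n * p]` and `x[n * p + 1]`
#' when it is (the inverse empirical CDF with averaging at jumps).  For
#' `p = 0.5` this is the textbook median: the middle value for odd `n`, the
#' midpoint of the central pair for even `n`.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @param probs probabilities in (0, 1).
#' @return numeric vector of the same length as `probs`; `NA` if `x` is
#'   empty after `NA` removal.
#' @examples
#' traj_quantile(c(4, 1, 3, 2), 0.5)  # 2.5
#' @export
traj_quantile <- function(x, probs = 0.5) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) {
    return(rep(NA_real_, length(probs)))
  }
  vapply(probs, function(p) {
    stopifnot(p > 0, p < 1)
    h <- n * p
    if (abs(h - round(h)) < 1e-9) {
      (x[round(h)] + x[round(h) + 1L]) / 2
    } else {
      x[ceiling(h)]
    }
  }, numeric(1))
}

#' @rdname traj_quantile
#' @export
traj_median <- function(x) traj_quantile(x, 0.5)

# stop() with sprintf formatting and no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x > 0
}

is_day <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x)
}

# split a data.frame by patient_id preserving first-appearance order
split_patients <- function(df) {
  split(df, factor(df$patient_id, levels = unique(df$patient_id)))
}

# rbind a list of data.frames, tolerating empties; returns template if all empty
rbind_all <- function(lst, template) {
  lst <- lst[vapply(lst, function(x) !is.null(x) && nrow(x) > 0L, logical(1))]
  if (length(lst) == 0L) {
    return(template)
  }
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}
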