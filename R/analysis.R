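# Use-case scoring layer: model-wise averaging, min-max scaling against a
# reference condition, phenotype scores on the Boolean-state and path-count
# channels, and Pearson correlation.

#' Model-wise average of per-state values
#'
#' @param values Numeric vector (Boolean states or signed path counts, one
#'   per stable state).
#' @return Arithmetic mean.
#' @export
model_average <- function(values) {
  if (length(values) == 0L) stop("no states to average", call. = FALSE)
  mean(values)
}

#' Min-max scale a score vector against a reference
#'
#' \code{scaled(v) = (v - reference) / (max(v, reference) - min(v, reference))},
#' so the reference condition maps exactly to 0 and all outputs lie in
#' [-1, 1]. A zero range yields all zeros.
#'
#' @param values Numeric vector.
#' @param reference Reference value (included in the range).
#' @return Scaled numeric vector.
#' @examples
#' minmax_scale(c(2, 4, 6), reference = 2)
#' @export
minmax_scale <- function(values, reference = 0) {
  stopifnot(length(values) >= 1L, is.finite(reference))
  rng <- range(c(values, reference))
  span <- rng[2] - rng[1]
  if (span == 0) return(rep(0, length(values)))
  (values - reference) / span
}

#' Phenotype scores from included stable states
#'
#' Computes a pro-phenotype score and an anti-phenotype resistance score
#' from the included states of one condition. On the Boolean-state channel
#' the scores are the mean local state of the pro node and the mean of
#' \code{1 - state} of the anti node; on the path-count channel they are the
#' mean signed count of the pro node and the mean negated signed count of
#' the anti node (the signed-count analogue of \code{1 - state}).
#'
#' @param mat Matrix of included states (rows) by nodes (columns): Boolean
#'   states for \code{channel = "state"}, signed path counts for
#'   \code{channel = "count"}. Typically rows selected by
#'   [filter_states_by_pert()].
#' @param pro_node,anti_node Phenotype readout column names.
#' @param channel \code{"state"} or \code{"count"}.
#' @param label Condition label used in error messages.
#' @return Named vector \code{c(pro, anti_resistance)}.
#' @export
phenotype_scores <- function(mat, pro_node, anti_node,
                             channel = c("state", "count"),
                             label = "condition") {
  channel <- match.arg(channel)
  stopifnot(is.matrix(mat))
  if (nrow(mat) == 0L) {
    stop("no included states for ", label, call. = FALSE)
  }
  missing <- setdiff(c(pro_node, anti_node), colnames(mat))
  if (length(missing)) {
    stop("unknown node(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pro <- mean(mat[, pro_node])
  anti <- if (channel == "state") {
    mean(1 - mat[, anti_node])
  } else {
    mean(-mat[, anti_node])
  }
  c(pro = pro, anti_resistance = anti)
}

#' Pearson correlation with a two-sided p value
#'
#' Sample Pearson correlation; the p value comes from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3) with
#'   non-degenerate variance.
#' @return List with elements \code{r} and \code{p}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
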