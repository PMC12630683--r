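# In-silico perturbations. Each perturbation adds a dedicated input node
# that influences the target, so the perturbed regime remains compatible
# with path construction (a bare 0/1 rule replacement would leave the
# target without any explanatory path).

pert_modes <- c(
  "non_additive_activation", "additive_activation",
  "non_additive_inhibition", "additive_inhibition"
)

pert_default_name <- function(target, mode, existing) {
  suffix <- if (grepl("activation", mode)) "_ACT" else "_INH"
  name <- paste0(target, suffix)
  k <- 1L
  while (name %in% existing) {
    k <- k + 1L
    name <- paste0(target, suffix, "_", k)
  }
  name
}

#' Apply a perturbation to a Boolean model
#'
#' Adds a dedicated perturbation input node \code{P} (rule \code{P, P}) and
#' rewrites the target's rule \code{R}:
#' \describe{
#'   \item{non_additive_activation}{\code{P} (regulation fully replaced)}
#'   \item{additive_activation}{\code{(R) | P}}
#'   \item{non_additive_inhibition}{\code{!P}}
#'   \item{additive_inhibition}{\code{(R) & !P}}
#' }
#' The perturbation node is a free input: both of its values are explored by
#' [fixed_points()], and the perturbed regime is selected afterwards with
#' [filter_states_by_pert()]. With the perturbation node inactive, the
#' additive modes reduce to the original rule.
#'
#' @param model A \code{boolean_model}.
#' @param target Node whose regulation is perturbed. Perturbing an input
#'   node is allowed (with a warning): this is how synthetic inputs are
#'   modeled.
#' @param mode One of \code{"non_additive_activation"},
#'   \code{"additive_activation"}, \code{"non_additive_inhibition"},
#'   \code{"additive_inhibition"}.
#' @param pert_node Name for the perturbation node; default
#'   \code{<target>_ACT} or \code{<target>_INH} (numeric suffix on
#'   collision).
#' @return The perturbed \code{boolean_model}, with attributes
#'   \code{"pert_node"}, \code{"pert_target"} and \code{"pert_mode"}.
#' @examples
#' m <- parse_bnet("I1, I1\nA, I1\nB, !A")
#' p <- apply_perturbation(m, "A", "additive_inhibition")
#' cat(write_bnet(p))
#' @export
apply_perturbation <- function(model, target, mode, pert_node = NULL) {
  stopifnot(inherits(model, "boolean_model"))
  mode <- match.arg(mode, pert_modes)
  if (!target %in% model$nodes) stop("unknown node: ", target, call. = FALSE)
  if (is.null(pert_node)) {
    pert_node <- pert_default_name(target, mode, model$nodes)
  } else if (pert_node %in% model$nodes) {
    stop("perturbation node name collides with existing node: ", pert_node,
      call. = FALSE
    )
  }
  if (!grepl(bp_name_rx, pert_node)) {
    stop("invalid perturbation node name: ", pert_node, call. = FALSE)
  }
  if (target %in% input_nodes(model)) {
    warning("perturbing input node '", target,
      "': it becomes a regulated surrogate of the perturbation node")
  }
  p <- list(type = "var", name = pert_node)
  old <- model$rules[[target]]
  new_rule <- switch(mode,
    non_additive_activation = p,
    additive_activation = list(type = "or", lhs = old, rhs = p),
    non_additive_inhibition = expr_not(p),
    additive_inhibition = list(type = "and", lhs = old, rhs = expr_not(p))
  )
  rules <- model$rules
  rules[[target]] <- new_rule
  rules[[pert_node]] <- p
  out <- new_boolean_model(c(model$nodes, pert_node), rules)
  validate_boolean_model(out)
  attr(out, "pert_node") <- pert_node
  attr(out, "pert_target") <- target
  attr(out, "pert_mode") <- mode
  out
}

#' Generate one perturbed model per eligible node and mode
#'
#' @param model A \code{boolean_model}.
#' @param exclude Nodes to skip (typically the inputs and the phenotype
#'   readouts).
#' @param modes Subset of the four perturbation modes; default the two
#'   additive modes used for drug-like perturbation screens.
#' @return List of entries \code{list(target, mode, pert_node, model)} in
#'   deterministic order (node order, then mode order). Empty, with a
#'   warning, if no node is eligible.
#' @export
batch_perturbations <- function(model, exclude = character(0),
                                modes = c("additive_activation", "additive_inhibition")) {
  stopifnot(inherits(model, "boolean_model"))
  modes <- match.arg(modes, pert_modes, several.ok = TRUE)
  eligible <- setdiff(model$nodes, exclude)
  if (!length(eligible)) {
    warning("no eligible nodes to perturb")
    return(list())
  }
  out <- list()
  for (n in eligible) {
    for (m in modes) {
      pm <- apply_perturbation(model, n, m)
      out[[length(out) + 1L]] <- list(
        target = n, mode = m,
        pert_node = attr(pm, "pert_node"), model = pm
      )
    }
  }
  out
}

#' Keep the stable states where a perturbation node has a required value
#'
#' A perturbation screen analyzes only the states in which the added
#' activator or inhibitor is effectively active, so the observed effect on
#' the target is attributable to the perturbation.
#'
#' @param states State matrix (rows are states, columns named by node).
#' @param pert_node Name of the perturbation node.
#' @param required_value 0 or 1 (default 1).
#' @return The matching rows, order preserved.
#' @export
filter_states_by_pert <- function(states, pert_node, required_value = 1L) {
  stopifnot(is.matrix(states))
  if (!pert_node %in% colnames(states)) {
    stop("unknown node: ", pert_node, call. = FALSE)
  }
  states[states[, pert_node] == required_value, , drop = FALSE]
}
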