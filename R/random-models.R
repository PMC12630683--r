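# Random Boolean model generation stratified by size and maximum in-degree,
# and the exhaustive path-enumeration scalability harness.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Generate randomized Boolean models
#'
#' Each model has \code{n_inputs} designated input nodes (self-identity
#' rules) and \code{n_nodes - n_inputs} regulated nodes. Every regulated
#' node draws an in-degree k uniformly from \code{1..k_max}, samples k
#' distinct regulators uniformly from all other nodes, negates each regulator
#' independently with probability 0.5, and chains the literals
#' left-associatively with independently uniform \code{&}/\code{|}
#' connectives. All randomness flows from the single seed, so the same
#' configuration always yields byte-identical models.
#'
#' @param n_nodes Total node count.
#' @param k_max Maximum in-degree of regulated nodes (must be < n_nodes).
#' @param n_inputs Number of designated inputs (default 3).
#' @param n_models Number of models to generate (default 20).
#' @param seed Integer seed.
#' @return List of \code{boolean_model} objects.
#' @export
generate_random_model <- function(n_nodes, k_max, n_inputs = 3L,
                                  n_models = 20L, seed = 1L) {
  stopifnot(n_inputs < n_nodes, k_max >= 1L, n_models >= 1L)
  if (k_max >= n_nodes) {
    stop("k_max must be smaller than the number of nodes", call. = FALSE)
  }
  inputs <- paste0("I", seq_len(n_inputs))
  others <- paste0("N", seq_len(n_nodes - n_inputs))
  nodes <- c(inputs, others)
  with_seed(seed, {
    lapply(seq_len(n_models), function(m) {
      rules <- list()
      for (n in inputs) rules[[n]] <- list(type = "var", name = n)
      for (n in others) {
        k <- sample.int(k_max, 1L)
        # a node never regulates itself: a self-identity draw would turn a
        # regulated node into an accidental input and break stratification
        regs <- sample(setdiff(nodes, n), k)
        neg <- runif(k) < 0.5
        lits <- lapply(seq_len(k), function(i) {
          v <- list(type = "var", name = regs[[i]])
          if (neg[[i]]) expr_not(v) else v
        })
        e <- lits[[1]]
        if (k > 1L) {
          ops <- sample(c("and", "or"), k - 1L, replace = TRUE)
          for (i in 2:k) e <- list(type = ops[[i - 1L]], lhs = e, rhs = lits[[i]])
        }
        rules[[n]] <- e
      }
      new_boolean_model(nodes, rules)
    })
  })
}

model_edge_count <- function(model) {
  sum(vapply(setdiff(model$nodes, input_nodes(model)), function(n) {
    length(expr_vars(model$rules[[n]]))
  }, numeric(1)))
}

#' Run the path-enumeration scalability protocol
#'
#' For every cell of the (\code{n_nodes} x \code{k_max}) grid, generates
#' \code{n_models} random models, enumerates their fixed points and counts
#' every node's paths in every stable state, recording per-state path
#' totals and wall-clock timings (informational only; every other field is
#' reproducible from the seed).
#'
#' @param n_nodes_grid,k_max_grid Integer vectors defining the sweep grid.
#' @param n_inputs,n_models,seed As in [generate_random_model()]; each grid
#'   cell uses \code{seed + <cell index>}.
#' @param loop_policy Passed to [count_model()].
#' @param max_trees Materialization cap; a model exceeding it is flagged
#'   and the run continues.
#' @param fp_method Fixed-point strategy (see [fixed_points()]).
#' @return Data frame with one row per model: \code{n_nodes}, \code{k_max},
#'   \code{model}, \code{seed}, \code{edge_count}, \code{n_stable_states},
#'   \code{paths_total}, \code{paths_per_state}, \code{elapsed},
#'   \code{flagged}.
#' @export
run_scalability <- function(n_nodes_grid, k_max_grid, n_inputs = 3L,
                            n_models = 20L, seed = 1L,
                            loop_policy = c("discard", "truncate"),
                            max_trees = 1e6,
                            fp_method = c("auto", "exhaustive", "search")) {
  loop_policy <- match.arg(loop_policy)
  fp_method <- match.arg(fp_method)
  rows <- list()
  cell <- 0L
  for (N in n_nodes_grid) {
    for (k in k_max_grid) {
      cell_seed <- seed + cell
      cell <- cell + 1L
      models <- generate_random_model(N, k, n_inputs, n_models, cell_seed)
      for (i in seq_along(models)) {
        mod <- models[[i]]
        t0 <- proc.time()[["elapsed"]]
        states <- fixed_points(mod, method = fp_method)
        flagged <- FALSE
        total <- 0
        if (nrow(states) > 0L) {
          tab <- tryCatch(
            count_model(mod,
              loop_policy = loop_policy, states = states,
              max_trees = max_trees
            ),
            error = function(e) {
              flagged <<- TRUE
              NULL
            }
          )
          if (!is.null(tab)) total <- sum(abs(tab$counts))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          n_nodes = N, k_max = k, model = i, seed = cell_seed,
          edge_count = model_edge_count(mod),
          n_stable_states = nrow(states),
          paths_total = total,
          paths_per_state = if (nrow(states) > 0L && !flagged) {
            total / nrow(states)
          } else {
            NA_real_
          },
          elapsed = proc.time()[["elapsed"]] - t0,
          flagged = flagged
        )
      }
    }
  }
  do.call(rbind, rows)
}
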