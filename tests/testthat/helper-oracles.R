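# Shared fixtures and independent oracles. Oracles deliberately evaluate
# bnet rule text through R's own parser (!, & and | are valid R operators),
# so they do not share the package's expression machinery.

mx_text <- paste(
  "targets, factors",
  "I1, I1",
  "I2, I2",
  "A, I1",
  "B, I1 & !I2",
  "C, A | B",
  "D, !C",
  sep = "\n"
)

mx_model <- function() parse_bnet(mx_text)

# Split bnet text into (name, rhs-string) pairs without the package parser.
bnet_lines <- function(text) {
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  lines <- lines[!grepl("^targets\\s*,\\s*factors$", lines, ignore.case = TRUE)]
  comma <- regexpr(",", lines, fixed = TRUE)
  data.frame(
    name = trimws(substr(lines, 1, comma - 1)),
    rhs = trimws(substr(lines, comma + 1, nchar(lines))),
    stringsAsFactors = FALSE
  )
}

# Evaluate a bnet rule string with R's parser over a list/data.frame of
# logical columns; returns a logical vector.
oracle_eval <- function(rhs, env) {
  v <- eval(parse(text = rhs)[[1]], env)
  n <- max(lengths(env), 1L)
  rep_len(as.logical(v), n)
}

all_assignments <- function(vars) {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), length(vars)))
  names(g) <- vars
  g
}

# Brute-force fixed points straight from the bnet text.
oracle_fixed_points <- function(text) {
  rl <- bnet_lines(text)
  g <- all_assignments(rl$name)
  ok <- rep(TRUE, nrow(g))
  for (i in seq_len(nrow(rl))) {
    ok <- ok & (oracle_eval(rl$rhs[i], g) == g[[rl$name[i]]])
  }
  m <- as.matrix(g[ok, , drop = FALSE]) * 1L
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m[order_states(m), , drop = FALSE]
}

order_states <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, as.data.frame(m))
}

# --- DNF oracles (truth-table based) ---------------------------------------

clause_holds <- function(clause, g) {
  v <- rep(TRUE, nrow(g))
  for (lit in clause) {
    neg <- startsWith(lit, "!")
    node <- sub("^!", "", lit)
    v <- v & (if (neg) !g[[node]] else g[[node]])
  }
  v
}

dnf_holds <- function(dnf, g) {
  v <- rep(FALSE, nrow(g))
  for (cl in dnf) v <- v | clause_holds(cl, g)
  v
}

# clause is an implicant of the function given by `truth` over grid g
is_implicant <- function(clause, truth, g) {
  all(truth[clause_holds(clause, g)])
}

# --- random generators (plain text, independent of the package) ------------

random_expr_text <- function(vars, depth = 3) {
  if (depth <= 0 || runif(1) < 0.3) {
    v <- sample(vars, 1)
    if (runif(1) < 0.4) paste0("!", v) else v
  } else {
    op <- sample(c("&", "|"), 1)
    lhs <- random_expr_text(vars, depth - 1)
    rhs <- random_expr_text(vars, depth - 1)
    s <- paste(lhs, op, rhs)
    if (runif(1) < 0.3) paste0("!(", s, ")") else s
  }
}

# Random model text: first n_inputs nodes are inputs, the rest draw
# regulators from any node (cycles allowed).
random_model_text <- function(n, k_max = 2, n_inputs = 2) {
  nodes <- paste0("V", seq_len(n))
  lines <- character(n)
  for (i in seq_len(n)) {
    if (i <= n_inputs) {
      lines[i] <- paste0(nodes[i], ", ", nodes[i])
    } else {
      k <- sample.int(k_max, 1)
      regs <- sample(nodes, k)
      lits <- ifelse(runif(k) < 0.5, paste0("!", regs), regs)
      rhs <- lits[1]
      if (k > 1) {
        for (j in 2:k) rhs <- paste(rhs, sample(c("&", "|"), 1), lits[j])
      }
      lines[i] <- paste0(nodes[i], ", ", rhs)
    }
  }
  paste(lines, collapse = "\n")
}

# Random acyclic model text: node i only draws regulators from nodes 1..i-1.
random_acyclic_model_text <- function(n, k_max = 2, n_inputs = 2) {
  nodes <- paste0("V", seq_len(n))
  lines <- character(n)
  for (i in seq_len(n)) {
    if (i <= n_inputs) {
      lines[i] <- paste0(nodes[i], ", ", nodes[i])
    } else {
      k <- sample.int(min(k_max, i - 1), 1)
      regs <- sample(nodes[seq_len(i - 1)], k)
      lits <- ifelse(runif(k) < 0.5, paste0("!", regs), regs)
      rhs <- lits[1]
      if (k > 1) {
        for (j in 2:k) rhs <- paste(rhs, sample(c("&", "|"), 1), lits[j])
      }
      lines[i] <- paste0(nodes[i], ", ", rhs)
    }
  }
  paste(lines, collapse = "\n")
}

# Linear cascade I -> X1 -> ... -> Xn
chain_model <- function(n) {
  lines <- c("I, I", "X1, I")
  if (n >= 2) {
    for (i in 2:n) lines <- c(lines, paste0("X", i, ", X", i - 1))
  }
  parse_bnet(paste(lines, collapse = "\n"))
}

# Rule text of one node as serialized by write_bnet.
expr_string_of <- function(model, node) {
  rl <- bnet_lines(write_bnet(model))
  rl$rhs[rl$name == node]
}

# Closed-form Pearson r for the oracle test.
oracle_pearson <- function(x, y) {
  xd <- x - mean(x)
  yd <- y - mean(y)
  sum(xd * yd) / sqrt(sum(xd^2) * sum(yd^2))
}
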