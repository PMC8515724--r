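#' Build a conditional probability table
#'
#' A CPT is stored as a numeric array whose first dimension is the node's own
#' states and whose remaining dimensions are its parents, in the order given.
#' For binary nodes the table can be supplied compactly as the probability of
#' state `"1"` for every parent configuration, with the *first* parent
#' varying fastest (the order produced by [expand.grid()]).
#'
#' @param node Node name.
#' @param parents Character vector of parent names (possibly empty).
#' @param p1 Numeric vector, length `2^length(parents)`: P(node = 1 | parent
#'   configuration). Ignored when `prob` is given.
#' @param prob Optional full array of probabilities (node states x parent
#'   states) for non-compact construction.
#' @param states Named list of state labels; defaults to binary `c("0","1")`
#'   for the node and all parents.
#' @return A CPT array with named dimnames, usable in [bayesnet()].
#' @examples
#' make_cpt("Y", "X", p1 = c(0.2, 0.9))  # P(Y=1|X=0)=.2, P(Y=1|X=1)=.9
#' @export
make_cpt <- function(node, parents = character(0), p1 = NULL, prob = NULL,
                     states = NULL) {
  if (is.null(states)) {
    states <- stats::setNames(rep(list(c("0", "1")), 1 + length(parents)),
                              c(node, parents))
  }
  if (is.null(prob)) {
    if (length(states[[node]]) != 2) {
      stop("compact `p1` form requires a binary node", call. = FALSE)
    }
    ncfg <- prod(lengths(states[parents]))
    if (length(p1) != ncfg) {
      stop(sprintf("`p1` must have length %d for %d parent(s)",
                   ncfg, length(parents)), call. = FALSE)
    }
    if (any(p1 < 0 | p1 > 1)) stop("probabilities outside [0,1]", call. = FALSE)
    prob <- rbind(1 - p1, p1)
  }
  dn <- states[c(node, parents)]
  array(as.numeric(prob), dim = lengths(dn), dimnames = dn)
}

#' Assemble a Bayesian network
#'
#' Couples a validated DAG with one CPT per node and checks coherence: CPT
#' scopes must equal `{node, parents}`, every conditional distribution must
#' sum to one, and (for networks of up to 12 binary-sized nodes) the induced
#' joint is verified to sum to one by exhaustive enumeration.
#'
#' @param dag A `bn_dag` from [validate_dag()].
#' @param cpts Named list of CPT arrays (see [make_cpt()]), one per node.
#' @param check Verify normalization invariants (default `TRUE`).
#' @return An object of class `bayesnet` with elements `dag`, `states` and
#'   `cpts` (each CPT permuted to canonical `(node, parents)` order).
#' @export
bayesnet <- function(dag, cpts, check = TRUE) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(cpts), dag$nodes)) {
    stop("need exactly one CPT per node; missing: ",
         paste(setdiff(dag$nodes, names(cpts)), collapse = ", "),
         call. = FALSE)
  }
  cpts <- cpts[dag$nodes]
  states <- list()
  for (v in dag$nodes) {
    cpt <- cpts[[v]]
    want <- c(v, dag_parents(dag, v))
    have <- f_vars(cpt)
    if (!setequal(have, want)) {
      stop(sprintf("CPT scope for '%s' is {%s}; DAG requires {%s}", v,
                   paste(have, collapse = ","), paste(want, collapse = ",")),
           call. = FALSE)
    }
    cpts[[v]] <- aperm(cpt, match(want, have))
    states[[v]] <- dimnames(cpts[[v]])[[1]]
  }
  bn <- structure(list(dag = dag, states = states, cpts = cpts),
                  class = "bayesnet")
  if (check) {
    for (v in dag$nodes) {
      cpt <- bn$cpts[[v]]
      if (any(cpt < 0 | cpt > 1)) {
        stop(sprintf("CPT for '%s' has probabilities outside [0,1]", v),
             call. = FALSE)
      }
      s <- f_marginal(cpt, setdiff(f_vars(cpt), v))
      if (any(abs(s - 1) > 1e-9)) {
        stop(sprintf("CPT for '%s' does not normalize over its states", v),
             call. = FALSE)
      }
    }
    if (sum(lengths(bn$states)) <= 24 && length(dag$nodes) <= 12) {
      tot <- as.numeric(f_marginal(Reduce(f_product, bn$cpts), character(0)))
      if (abs(tot - 1) > 1e-9) {
        stop("induced joint distribution does not sum to 1", call. = FALSE)
      }
    }
  }
  bn
}

#' @export
print.bayesnet <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges\n")
  for (v in x$dag$nodes) {
    pa <- dag_parents(x$dag, v)
    cat(sprintf("  %s | %s\n", v,
                if (length(pa)) paste(pa, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Fit conditional probability tables from data
#'
#' Estimates each node's CPT by (optionally smoothed) maximum likelihood:
#' `(n(x, pa) + pseudocount) / (n(pa) + pseudocount * |states|)`. With
#' `pseudocount = 0` this is the MLE, and any parent configuration that never
#' occurs in the data is an error rather than a silently uniform row.
#'
#' @param dag A `bn_dag`.
#' @param data Data frame whose columns cover the DAG nodes; values are
#'   matched against `states` labels (integers 0/1 work for the default).
#' @param pseudocount Non-negative Laplace smoothing constant (default 0).
#' @param states Named list of state labels per node; default binary
#'   `c("0","1")` everywhere.
#' @return A [bayesnet()].
#' @export
fit_cpts <- function(dag, data, pseudocount = 0, states = NULL) {
  stopifnot(inherits(dag, "bn_dag"), pseudocount >= 0)
  if (!all(dag$nodes %in% names(data))) {
    stop("data lack column(s): ",
         paste(setdiff(dag$nodes, names(data)), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(states)) {
    states <- stats::setNames(rep(list(c("0", "1")), length(dag$nodes)),
                              dag$nodes)
  }
  cpts <- list()
  for (v in dag$nodes) {
    vars <- c(v, dag_parents(dag, v))
    cols <- stats::setNames(lapply(vars, function(u) {
      x <- factor(as.character(data[[u]]), levels = states[[u]])
      if (anyNA(x)) {
        stop(sprintf("column '%s' contains values outside its states", u),
             call. = FALSE)
      }
      x
    }), vars)
    counts <- table(cols) + pseudocount
    denom <- f_marginal(counts, setdiff(vars, v))
    if (length(vars) > 1) {
      if (any(denom == 0)) {
        i <- which(denom == 0, arr.ind = TRUE)
        cfg <- paste(f_vars(denom), "=",
                     mapply(function(d, j) d[j], dimnames(denom),
                            i[1, ]), collapse = ", ")
        stop(sprintf(
          "no observations for parent configuration {%s} of node '%s'; %s",
          cfg, v, "use a positive pseudocount or more data"), call. = FALSE)
      }
      cpt <- counts / rep(as.vector(denom), each = length(states[[v]]))
    } else {
      if (denom == 0) stop(sprintf("no observations for node '%s'", v),
                           call. = FALSE)
      cpt <- counts / denom
    }
    cpts[[v]] <- array(as.numeric(cpt), dim = dim(counts),
                       dimnames = dimnames(counts))
  }
  bayesnet(dag, cpts, check = FALSE)
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorized joint: the product over nodes of
#' P(node = x | parents = pi).
#'
#' @param bn A [bayesnet()].
#' @param assignment Named list/vector assigning a state to *every* node.
#' @return A probability.
#' @export
joint_probability <- function(bn, assignment) {
  missing <- setdiff(bn$dag$nodes, names(assignment))
  if (length(missing)) {
    stop("assignment must cover every node; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  p <- 1
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    vars <- f_vars(cpt)
    idx <- vapply(seq_along(vars), function(i) {
      j <- match(as.character(assignment[[vars[i]]]), dimnames(cpt)[[i]])
      if (is.na(j)) {
        stop(sprintf("unknown state '%s' for variable '%s'",
                     assignment[[vars[i]]], vars[i]), call. = FALSE)
      }
      j
    }, integer(1))
    p <- p * cpt[matrix(idx, nrow = 1)]
  }
  unname(p)
}

#' Serialize a Bayesian network to JSON
#'
#' The format stores nodes, state labels, the edge list, and per node its
#' parent order plus the CPT flattened row-wise: one row per parent
#' configuration (last-listed parent cycling fastest), each row listing the
#' node-state probabilities in state order. Round-trips losslessly through
#' [read_bn_json()].
#'
#' @param bn A [bayesnet()].
#' @param path Output file path.
#' @export
write_bn_json <- function(bn, path) {
  cpts <- lapply(bn$dag$nodes, function(v) {
    cpt <- bn$cpts[[v]]
    pa <- dag_parents(bn$dag, v)
    # permute to (node, reversed parents) so that flattening yields one row
    # of node-state probabilities per parent configuration, with the
    # last-listed parent varying fastest across rows
    ord <- match(c(v, rev(pa)), f_vars(cpt))
    list(parents = pa, probs = as.vector(aperm(cpt, ord)))
  })
  names(cpts) <- bn$dag$nodes
  obj <- list(nodes = bn$dag$nodes,
              states = bn$states,
              edges = apply(bn$dag$edges, 1, as.list),
              cpts = cpts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @return `read_bn_json()` returns the reconstructed [bayesnet()].
#' @export
read_bn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges)) {
    if (is.data.frame(obj$edges)) {
      cbind(obj$edges$from, obj$edges$to)
    } else {
      do.call(rbind, lapply(obj$edges, function(e) c(e$from, e$to)))
    }
  }
  dag <- validate_dag(obj$nodes, edges)
  states <- lapply(obj$states, as.character)
  cpts <- list()
  for (v in obj$nodes) {
    pa <- as.character(obj$cpts[[v]]$parents)
    dn <- states[c(v, rev(pa))]
    arr <- array(obj$cpts[[v]]$probs, dim = lengths(dn), dimnames = dn)
    cpts[[v]] <- aperm(arr, match(c(v, pa), f_vars(arr)))
  }
  bayesnet(dag, cpts)
}
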