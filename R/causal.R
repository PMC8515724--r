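# Interventions via graph surgery, the backdoor adjustment formula, and
# average causal effects.

#' Graph surgery: the do-operator
#'
#' Returns the mutilated network that represents `do(treatment = state)`:
#' every edge into the treatment is removed and its CPT is replaced by a
#' point mass on the chosen state. All other CPTs are untouched.
#'
#' @param bn A [bayesnet()].
#' @param treatment Node to intervene on.
#' @param state State it is forced to.
#' @return A new [bayesnet()].
#' @export
intervene <- function(bn, treatment, state) {
  if (!treatment %in% bn$dag$nodes) {
    stop(sprintf("unknown node '%s'", treatment), call. = FALSE)
  }
  states <- bn$states[[treatment]]
  if (!as.character(state) %in% states) {
    stop(sprintf("unknown state '%s' for variable '%s'", state, treatment),
         call. = FALSE)
  }
  keep <- bn$dag$edges[, "to"] != treatment
  dag <- validate_dag(bn$dag$nodes, bn$dag$edges[keep, , drop = FALSE])
  p <- as.numeric(states == as.character(state))
  cpts <- bn$cpts
  cpts[[treatment]] <- array(p, dim = length(states),
                             dimnames = stats::setNames(list(states),
                                                        treatment))
  bayesnet(dag, cpts, check = FALSE)
}

#' Backdoor adjustment formula
#'
#' Computes `sum_z P(outcome | treatment, Z = z) P(Z = z)` by exact
#' inference on the *unmutilated* network: the observational conditional is
#' taken within each stratum of the adjustment set and averaged over the
#' strata distribution.
#'
#' @param bn A [bayesnet()].
#' @param outcome,treatment Named lists `list(var =, state =)` (or
#'   two-element vectors `c(var, state)`).
#' @param adjustment_set Character vector of adjustment variables (may be
#'   empty, in which case the plain conditional is returned).
#' @param check_backdoor If `TRUE`, warn when the adjustment set does not
#'   block every backdoor path from treatment to outcome (d-separation in
#'   the graph with the treatment's outgoing edges removed). Default
#'   `FALSE`: the study's own published sets are taken as given.
#' @return The interventional probability estimate, a number in \[0, 1\].
#' @export
adjustment_probability <- function(bn, outcome, treatment,
                                   adjustment_set = character(0),
                                   check_backdoor = FALSE) {
  outcome <- as_var_state(outcome)
  treatment <- as_var_state(treatment)
  if (outcome$var == treatment$var) {
    stop("outcome and treatment must differ", call. = FALSE)
  }
  if (any(adjustment_set %in% c(outcome$var, treatment$var))) {
    stop("adjustment set must exclude outcome and treatment", call. = FALSE)
  }
  if (check_backdoor &&
      !is_backdoor_admissible(bn$dag, treatment$var, outcome$var,
                              adjustment_set)) {
    warning(sprintf(
      "adjustment set {%s} does not block every backdoor path from %s to %s",
      paste(adjustment_set, collapse = ", "), treatment$var, outcome$var),
      call. = FALSE)
  }
  if (!length(adjustment_set)) {
    p <- query(bn, outcome$var,
               stats::setNames(list(treatment$state), treatment$var))
    return(unname(p[as.character(outcome$state)]))
  }
  pz <- query_joint(bn, adjustment_set)
  grid <- expand.grid(bn$states[adjustment_set], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  total <- 0
  for (i in seq_len(nrow(grid))) {
    z <- as.list(grid[i, , drop = FALSE])
    wz <- if (length(adjustment_set) == 1) {
      pz[[z[[1]]]]
    } else {
      pz[matrix(vapply(adjustment_set, function(v) {
        match(z[[v]], bn$states[[v]])
      }, integer(1)), nrow = 1)]
    }
    if (wz == 0) next
    ev <- c(stats::setNames(list(treatment$state), treatment$var), z)
    cond <- tryCatch(query(bn, outcome$var, ev), error = function(e) {
      stop(sprintf(
        "positivity violation: treatment %s=%s never occurs in stratum {%s}",
        treatment$var, treatment$state,
        paste(names(z), unlist(z), sep = "=", collapse = ", ")),
        call. = FALSE)
    })
    total <- total + wz * cond[[as.character(outcome$state)]]
  }
  unname(total)
}

as_var_state <- function(x) {
  if (is.list(x) && !is.null(x$var)) {
    list(var = as.character(x$var), state = as.character(x$state))
  } else if (length(x) == 2) {
    list(var = as.character(x[[1]]), state = as.character(x[[2]]))
  } else {
    stop("expected list(var =, state =) or c(var, state)", call. = FALSE)
  }
}

#' Backdoor admissibility of an adjustment set
#'
#' A set Z is admissible for estimating the effect of `treatment` on
#' `outcome` when it contains no descendant of the treatment and d-separates
#' treatment from outcome in the graph with the treatment's *outgoing* edges
#' removed.
#'
#' @param dag A `bn_dag`.
#' @param treatment,outcome Node names.
#' @param set Character vector of adjustment variables.
#' @return Logical.
#' @export
is_backdoor_admissible <- function(dag, treatment, outcome,
                                   set = character(0)) {
  g <- as_igraph(dag)
  desc <- setdiff(names(igraph::subcomponent(g, treatment, mode = "out")),
                  treatment)
  if (any(set %in% desc)) return(FALSE)
  keep <- dag$edges[, "from"] != treatment
  pruned <- validate_dag(dag$nodes, dag$edges[keep, , drop = FALSE])
  d_separated(pruned, treatment, outcome, set)
}

#' Specify an intervention contrast
#'
#' @param outcome Named list `list(var =, state =)`: the outcome event Y = y.
#' @param treatment Treatment variable name.
#' @param treatment_states Ordered pair of treatment states `(x_i, x_j)`;
#'   the effect reported is `P(Y=y|do(X=x_i)) - P(Y=y|do(X=x_j))`.
#' @param adjustment_set Character vector of adjustment variables.
#' @return An `intervention_query` object.
#' @export
intervention_query <- function(outcome, treatment,
                               treatment_states = c("1", "0"),
                               adjustment_set = character(0)) {
  outcome <- as_var_state(outcome)
  stopifnot(length(treatment_states) == 2)
  if (outcome$var == treatment) {
    stop("outcome and treatment must differ", call. = FALSE)
  }
  if (any(adjustment_set %in% c(outcome$var, treatment))) {
    stop("adjustment set must exclude outcome and treatment", call. = FALSE)
  }
  structure(list(outcome = outcome, treatment = treatment,
                 treatment_states = as.character(treatment_states),
                 adjustment_set = adjustment_set),
            class = "intervention_query")
}

#' Average causal effect of a binary contrast
#'
#' `ACE = P(Y=y | do(X=x_i)) - P(Y=y | do(X=x_j))`, with each interventional
#' probability estimated by the backdoor adjustment formula over the query's
#' adjustment set.
#'
#' @param bn A [bayesnet()].
#' @param q An [intervention_query()].
#' @param check_backdoor Passed to [adjustment_probability()].
#' @return An `ace_result`: the query plus `p_do_i`, `p_do_j` and
#'   `ace = p_do_i - p_do_j`.
#' @export
average_causal_effect <- function(bn, q, check_backdoor = FALSE) {
  stopifnot(inherits(q, "intervention_query"))
  p <- vapply(q$treatment_states, function(s) {
    adjustment_probability(bn, q$outcome,
                           list(var = q$treatment, state = s),
                           q$adjustment_set,
                           check_backdoor = check_backdoor)
  }, numeric(1))
  structure(list(query = q, p_do_i = unname(p[1]), p_do_j = unname(p[2]),
                 ace = unname(p[1] - p[2])),
            class = "ace_result")
}

#' @export
print.ace_result <- function(x, ...) {
  q <- x$query
  cat(sprintf(
    "ACE = P(%s=%s | do(%s=%s)) - P(%s=%s | do(%s=%s))  [adjusted for: %s]\n",
    q$outcome$var, q$outcome$state, q$treatment, q$treatment_states[1],
    q$outcome$var, q$outcome$state, q$treatment, q$treatment_states[2],
    if (length(q$adjustment_set)) paste(q$adjustment_set, collapse = ", ")
    else "(nothing)"))
  cat(sprintf("    = %.4f - %.4f = %.4f\n", x$p_do_i, x$p_do_j, x$ace))
  invisible(x)
}
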