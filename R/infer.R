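# Exact inference: sum-product variable elimination for conditional queries
# and max-product elimination with traceback for MAP completions. Both have
# enumeration counterparts used as slow reference paths.

check_evidence <- function(bn, evidence) {
  evidence <- as.list(evidence)
  unknown <- setdiff(names(evidence), bn$dag$nodes)
  if (length(unknown)) {
    stop("evidence names unknown node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (v in names(evidence)) {
    if (!as.character(evidence[[v]]) %in% bn$states[[v]]) {
      stop(sprintf("unknown state '%s' for variable '%s'",
                   evidence[[v]], v), call. = FALSE)
    }
  }
  evidence
}

#' Exact joint distribution over a set of query variables
#'
#' Sums the factorized joint over all unobserved non-query variables by
#' variable elimination, then normalizes by the evidence probability.
#'
#' @param bn A [bayesnet()].
#' @param targets Character vector of query variables.
#' @param evidence Named list/vector of observed states (may be empty).
#' @return A probability array over the target variables (a named vector for
#'   a single target), summing to 1.
#' @export
query_joint <- function(bn, targets, evidence = NULL) {
  evidence <- check_evidence(bn, evidence)
  stopifnot(all(targets %in% bn$dag$nodes))
  free_targets <- setdiff(targets, names(evidence))
  factors <- lapply(bn$cpts, f_reduce, evidence = evidence)
  const <- 1
  scal <- vapply(factors, function(f) is.null(dim(f)), TRUE)
  const <- prod(1, unlist(factors[scal]))
  factors <- factors[!scal]
  hidden <- setdiff(bn$dag$nodes, c(free_targets, names(evidence)))
  ord <- ve_elimination_order(lapply(factors, f_vars), bn$states, hidden)
  for (v in ord) {
    inv <- vapply(factors, function(f) v %in% f_vars(f), TRUE)
    if (!any(inv)) next
    psi <- Reduce(f_product, factors[inv])
    tau <- f_marginal(psi, setdiff(f_vars(psi), v))
    factors <- factors[!inv]
    if (is.null(dim(tau))) const <- const * tau else factors <- c(factors, list(tau))
  }
  joint <- if (length(factors)) Reduce(f_product, factors) * const else const
  total <- if (is.null(dim(joint))) joint else sum(joint)
  if (total == 0) {
    stop("impossible evidence: the observed configuration has probability 0",
         call. = FALSE)
  }
  if (!length(free_targets)) {
    # every target is evidenced: point mass
    dn <- lapply(bn$states[targets], identity)
    out <- array(0, dim = lengths(dn), dimnames = dn)
    idx <- vapply(targets, function(v) {
      match(as.character(evidence[[v]]), bn$states[[v]])
    }, integer(1))
    out[matrix(idx, nrow = 1)] <- 1
    return(if (length(targets) == 1) drop_to_vector(out) else out)
  }
  joint <- f_expand(joint, targets,
                    c(bn$states[free_targets],
                      point_states(bn, evidence, targets)))
  # evidenced targets enter as point masses
  for (v in intersect(targets, names(evidence))) {
    mask <- array(0, dim = lengths(bn$states[v]),
                  dimnames = bn$states[v])
    mask[match(as.character(evidence[[v]]), bn$states[[v]])] <- 1
    joint <- f_product(joint, mask)
    joint <- aperm(joint, match(targets, f_vars(joint)))
  }
  out <- joint / total
  if (length(targets) == 1) drop_to_vector(out) else out
}

point_states <- function(bn, evidence, targets) {
  bn$states[intersect(targets, names(evidence))]
}

drop_to_vector <- function(arr) {
  stats::setNames(as.vector(arr), dimnames(arr)[[1]])
}

#' Exact conditional query P(target | evidence)
#'
#' @inheritParams query_joint
#' @param target Single query variable.
#' @param method `"ve"` (variable elimination, default) or `"enumeration"`
#'   (explicit sum over all completions; reference path).
#' @return Named probability vector over the target's states.
#' @examples
#' dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
#' bn <- bayesnet(dag, list(A = make_cpt("A", p1 = 0.5),
#'                          B = make_cpt("B", "A", p1 = c(0.1, 0.9))))
#' query(bn, "A", evidence = list(B = "1"))  # P(A=1|B=1) = 0.9
#' @export
query <- function(bn, target, evidence = NULL,
                  method = c("ve", "enumeration")) {
  method <- match.arg(method)
  stopifnot(length(target) == 1)
  if (method == "ve") return(query_joint(bn, target, evidence))
  evidence <- check_evidence(bn, evidence)
  if (target %in% names(evidence)) {
    out <- stats::setNames(rep(0, length(bn$states[[target]])),
                           bn$states[[target]])
    out[as.character(evidence[[target]])] <- 1
    return(out)
  }
  free <- setdiff(bn$dag$nodes, names(evidence))
  grid <- expand.grid(bn$states[free], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  p <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(bn, c(as.list(grid[i, , drop = FALSE]), evidence))
  }, numeric(1))
  tot <- sum(p)
  if (tot == 0) {
    stop("impossible evidence: the observed configuration has probability 0",
         call. = FALSE)
  }
  out <- vapply(bn$states[[target]],
                function(s) sum(p[grid[[target]] == s]), numeric(1))
  out / tot
}

#' Most probable completion (MAP assignment)
#'
#' Finds the completion of the evidence that maximizes the joint
#' probability, by max-product variable elimination with traceback. Ties
#' (within 1e-12) trigger a warning and are resolved canonically: the
#' lexicographically smallest assignment by variable name, earlier states
#' first, found by exhaustive enumeration.
#'
#' @inheritParams query_joint
#' @param method `"ve"` (max-product, default) or `"enumeration"`.
#' @return A named list: `assignment` (full named state list) and
#'   `probability` (its joint probability).
#' @export
map_assignment <- function(bn, evidence = NULL,
                           method = c("ve", "enumeration")) {
  method <- match.arg(method)
  evidence <- check_evidence(bn, evidence)
  if (method == "enumeration") return(map_enumerate(bn, evidence, warn = FALSE))
  factors <- lapply(bn$cpts, f_reduce, evidence = evidence)
  scal <- vapply(factors, function(f) is.null(dim(f)), TRUE)
  const <- prod(1, unlist(factors[scal]))
  factors <- factors[!scal]
  free <- setdiff(bn$dag$nodes, names(evidence))
  ord <- ve_elimination_order(lapply(factors, f_vars), bn$states, free)
  policies <- list()
  tie <- FALSE
  for (v in ord) {
    inv <- vapply(factors, function(f) v %in% f_vars(f), TRUE)
    psi <- if (any(inv)) Reduce(f_product, factors[inv]) else {
      array(1, dim = lengths(bn$states[v]), dimnames = bn$states[v])
    }
    mo <- f_max_out(psi, v)
    tie <- tie || mo$tie
    policies[[v]] <- mo
    factors <- factors[!inv]
    if (!is.null(dim(mo$p))) {
      factors <- c(factors, list(mo$p))
    } else {
      const <- const * mo$p
    }
  }
  if (const == 0 && length(free)) {
    # all-zero max can only arise from impossible evidence
    stop("impossible evidence: the observed configuration has probability 0",
         call. = FALSE)
  }
  if (tie) {
    warning("MAP is not unique; returning the lexicographically smallest ",
            "maximizer (variables alphabetically, earlier states first)",
            call. = FALSE)
    return(map_enumerate(bn, evidence, warn = FALSE))
  }
  assignment <- as.list(evidence)
  for (v in rev(ord)) {
    mo <- policies[[v]]
    if (is.null(dim(mo$arg))) {
      k <- mo$arg
    } else {
      scope <- f_vars(mo$arg)
      idx <- vapply(scope, function(u) {
        match(as.character(assignment[[u]]), bn$states[[u]])
      }, integer(1))
      k <- mo$arg[matrix(idx, nrow = 1)]
    }
    assignment[[v]] <- mo$states[k]
  }
  assignment <- assignment[bn$dag$nodes]
  p <- joint_probability(bn, assignment)
  if (p == 0) {
    stop("impossible evidence: the observed configuration has probability 0",
         call. = FALSE)
  }
  list(assignment = assignment, probability = p)
}

map_enumerate <- function(bn, evidence, warn = TRUE, tol = 1e-12) {
  free <- sort(setdiff(bn$dag$nodes, names(evidence)))
  if (!length(free)) {
    p <- joint_probability(bn, evidence)
    if (p == 0) {
      stop("impossible evidence: the observed configuration has probability 0",
           call. = FALSE)
    }
    return(list(assignment = as.list(evidence)[bn$dag$nodes],
                probability = p))
  }
  # lexicographic row order: first variable is the slowest-varying
  grid <- expand.grid(rev(bn$states[free]), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, rev(seq_along(free)), drop = FALSE]
  p <- vapply(seq_len(nrow(grid)), function(i) {
    joint_probability(bn, c(as.list(grid[i, , drop = FALSE]), evidence))
  }, numeric(1))
  if (max(p) == 0) {
    stop("impossible evidence: the observed configuration has probability 0",
         call. = FALSE)
  }
  hit <- which(p >= max(p) - tol)
  if (warn && length(hit) > 1) {
    warning("MAP is not unique; returning the lexicographically smallest ",
            "maximizer", call. = FALSE)
  }
  best <- c(as.list(grid[hit[1], , drop = FALSE]), evidence)
  best <- lapply(best, as.character)[bn$dag$nodes]
  list(assignment = best, probability = p[hit[1]])
}
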