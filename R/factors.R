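# Internal factor algebra for exact discrete inference.
#
# A factor is a numeric array whose dimnames are the state labels of each
# variable and whose dimnames *names* are the variable names. A factor with
# no variables degenerates to a plain numeric scalar; callers accumulate
# those into a constant.

f_vars <- function(f) names(dimnames(f))

f_states <- function(f) dimnames(f)

# Replicate `f` over the superset `vars` (states looked up in `states`),
# returning an array whose dimensions follow the order of `vars`.
f_expand <- function(f, vars, states) {
  fv <- f_vars(f)
  miss <- setdiff(vars, fv)
  if (length(miss)) {
    extra <- states[miss]
    dn <- c(dimnames(f), extra)
    f <- array(rep(as.vector(f), times = prod(lengths(extra))),
               dim = lengths(dn), dimnames = dn)
  }
  aperm(f, match(vars, f_vars(f)))
}

f_product <- function(a, b) {
  if (is.null(dim(a))) return(b * as.numeric(a))
  if (is.null(dim(b))) return(a * as.numeric(b))
  vars <- union(f_vars(a), f_vars(b))
  states <- c(dimnames(a), dimnames(b))
  states <- states[!duplicated(names(states))]
  f_expand(a, vars, states) * f_expand(b, vars, states)
}

# Sum out every variable of `f` not in `keep`; returns a scalar when `keep`
# is empty.
f_marginal <- function(f, keep) {
  vars <- f_vars(f)
  keep <- intersect(keep, vars)
  dropv <- setdiff(vars, keep)
  if (!length(dropv)) return(aperm(f, match(keep, vars)))
  if (!length(keep)) return(sum(f))
  g <- aperm(f, match(c(keep, dropv), vars))
  dn <- dimnames(g)[seq_along(keep)]
  dim(g) <- c(prod(lengths(dn)), length(g) / prod(lengths(dn)))
  array(rowSums(g), dim = lengths(dn), dimnames = dn)
}

# Condition on the entries of `evidence` (named list/vector of state labels)
# that intersect the factor's scope, dropping those dimensions.
f_reduce <- function(f, evidence) {
  vars <- f_vars(f)
  ev <- evidence[intersect(names(evidence), vars)]
  if (!length(ev)) return(f)
  idx <- lapply(seq_along(vars), function(i) {
    v <- vars[i]
    if (v %in% names(ev)) {
      j <- match(as.character(ev[[v]]), dimnames(f)[[i]])
      if (is.na(j)) {
        stop(sprintf("unknown state '%s' for variable '%s'", ev[[v]], v),
             call. = FALSE)
      }
      j
    } else {
      seq_len(dim(f)[i])
    }
  })
  g <- do.call(`[`, c(list(f), idx, list(drop = FALSE)))
  keepv <- setdiff(vars, names(ev))
  if (!length(keepv)) return(as.numeric(g))
  dn <- dimnames(f)[keepv]
  array(as.vector(g), dim = lengths(dn), dimnames = dn)
}

# Maximize `var` out of `f`. Returns the max-factor over the remaining scope,
# the per-configuration argmax (state index, first-state-wins on exact ties),
# and whether any configuration was tied within `tol`.
f_max_out <- function(f, var, tol = 1e-12) {
  vars <- f_vars(f)
  rest <- setdiff(vars, var)
  g <- aperm(f, match(c(rest, var), vars))
  k <- dim(f)[match(var, vars)]
  m <- matrix(as.vector(g), ncol = k)
  am <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), am)]
  tie <- any(rowSums(abs(m - mx) <= tol) > 1L)
  states <- dimnames(f)[[var]]
  if (!length(rest)) {
    return(list(p = as.numeric(mx), arg = am, states = states, tie = tie))
  }
  dn <- dimnames(f)[rest]
  list(p = array(mx, dim = lengths(dn), dimnames = dn),
       arg = array(am, dim = lengths(dn), dimnames = dn),
       states = states, tie = tie)
}

# Greedy elimination-order heuristic: repeatedly pick the hidden variable
# whose combined bucket factor would be smallest.
ve_elimination_order <- function(scopes, states, hidden) {
  order <- character(0)
  scopes <- lapply(scopes, identity)
  while (length(hidden)) {
    cost <- vapply(hidden, function(v) {
      sc <- unique(unlist(scopes[vapply(scopes, function(s) v %in% s, TRUE)]))
      prod(lengths(states[sc]))
    }, numeric(1))
    v <- hidden[which.min(cost)]
    involved <- vapply(scopes, function(s) v %in% s, TRUE)
    merged <- setdiff(unique(unlist(scopes[involved])), v)
    scopes <- c(scopes[!involved], if (length(merged)) list(merged))
    hidden <- setdiff(hidden, v)
    order <- c(order, v)
  }
  order
}
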