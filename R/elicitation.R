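# Expert-elicitation of the network structure, and the pairwise
# correlation table with spurious-correlation annotation.

#' Read per-expert edge assertions
#'
#' One row per expert per asserted directed edge, with columns `expert_id`,
#' `profession`, `source`, `target`.
#'
#' @param path CSV file path.
#' @param nodes Attribute set the endpoints must come from (default: the
#'   seven study attributes).
#' @return An `expert_surveys` data frame.
#' @export
read_expert_surveys <- function(path, nodes = binary_columns) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("expert_id", "profession", "source", "target")
  if (!all(need %in% names(df))) {
    stop("survey file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- !(df$source %in% nodes & df$target %in% nodes)
  if (any(bad)) {
    stop("asserted edge endpoint(s) outside the attribute set: ",
         paste(unique(c(df$source[bad], df$target[bad])), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$source == df$target)) {
    stop("self-loop assertion in survey file", call. = FALSE)
  }
  df <- df[!duplicated(df[c("expert_id", "source", "target")]), ]
  class(df) <- c("expert_surveys", "data.frame")
  df
}

#' Aggregate expert assertions into a consensus DAG
#'
#' An edge enters the consensus graph when at least `vote_threshold` of the
#' experts asserted it. When both directions pass, the higher-voted
#' direction is kept (an exact tie drops both, with a warning). Should the
#' voted graph still contain a directed cycle, the lowest-voted edge inside
#' a cycle is dropped repeatedly until the graph is acyclic; every repair is
#' recorded.
#'
#' @param surveys An `expert_surveys` data frame (see
#'   [read_expert_surveys()]).
#' @param vote_threshold Fraction of experts required (default 0.5,
#'   simple majority).
#' @param nodes Node set of the resulting DAG.
#' @return List with `dag` (a `bn_dag`), `votes` (per-edge counts with an
#'   `included` flag) and `dropped` (edges removed by direction conflicts or
#'   cycle repair).
#' @export
aggregate_consensus_dag <- function(surveys, vote_threshold = 0.5,
                                    nodes = binary_columns) {
  if (!NROW(surveys)) stop("no surveys supplied", call. = FALSE)
  if (vote_threshold <= 0 || vote_threshold > 1) {
    stop("vote_threshold must be in (0, 1]", call. = FALSE)
  }
  n_experts <- length(unique(surveys$expert_id))
  votes <- stats::aggregate(list(votes = surveys$expert_id),
                            by = list(from = surveys$source,
                                      to = surveys$target),
                            FUN = function(x) length(unique(x)))
  votes$fraction <- votes$votes / n_experts
  votes$included <- votes$fraction >= vote_threshold
  dropped <- list()
  # direction conflicts among passing edges
  for (i in which(votes$included)) {
    j <- which(votes$from == votes$to[i] & votes$to == votes$from[i] &
                 votes$included)
    if (length(j) && votes$included[i]) {
      if (votes$votes[i] == votes$votes[j]) {
        warning(sprintf(
          "tied votes for %s->%s and %s->%s; excluding both directions",
          votes$from[i], votes$to[i], votes$from[j], votes$to[j]),
          call. = FALSE)
        votes$included[c(i, j)] <- FALSE
        dropped <- c(dropped,
                     list(list(from = votes$from[i], to = votes$to[i],
                               reason = "direction tie"),
                          list(from = votes$from[j], to = votes$to[j],
                               reason = "direction tie")))
      } else {
        lose <- if (votes$votes[i] < votes$votes[j]) i else j
        votes$included[lose] <- FALSE
        dropped <- c(dropped,
                     list(list(from = votes$from[lose], to = votes$to[lose],
                               reason = "lower-voted direction")))
      }
    }
  }
  # cycle repair: drop the lowest-voted edge inside a strongly connected
  # component until acyclic
  repeat {
    inc <- votes[votes$included, , drop = FALSE]
    g <- dag_igraph(nodes, as.matrix(inc[c("from", "to")]))
    if (igraph::is_dag(g)) break
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which(comp$csize > 1)[1]]
    in_cycle <- which(votes$included & votes$from %in% cyc &
                        votes$to %in% cyc)
    lose <- in_cycle[which.min(votes$votes[in_cycle])]
    message(sprintf("cycle repair: dropping %s->%s (%d votes)",
                    votes$from[lose], votes$to[lose], votes$votes[lose]))
    votes$included[lose] <- FALSE
    dropped <- c(dropped, list(list(from = votes$from[lose],
                                    to = votes$to[lose],
                                    reason = "cycle repair")))
  }
  inc <- votes[votes$included, , drop = FALSE]
  list(dag = validate_dag(nodes, as.matrix(inc[c("from", "to")])),
       votes = votes, dropped = dropped, n_experts = n_experts)
}

#' Pairwise Pearson correlations of the binary table
#'
#' For 0/1 variables the Pearson product-moment coefficient coincides with
#' the phi coefficient.
#'
#' @param data A `binary_table` (0/1 data frame).
#' @return A `correlation_table`: list with matrix `r` and logical matrix
#'   `sc` (all `FALSE` until [annotate_spurious()] is applied).
#' @export
correlation_table <- function(data) {
  m <- as.matrix(as.data.frame(data))
  storage.mode(m) <- "numeric"
  const <- colnames(m)[apply(m, 2, function(x) stats::var(x) == 0)]
  if (length(const)) {
    stop("constant column(s) have undefined correlation: ",
         paste(const, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  structure(list(r = r,
                 sc = matrix(FALSE, nrow(r), ncol(r),
                             dimnames = dimnames(r))),
            class = "correlation_table")
}

#' Flag spurious correlations against a causal DAG
#'
#' A pair is marked SC (spurious correlation) when the DAG contains no
#' directed path between the two attributes in either direction, so their
#' observed association is not attributed to causation. This reachability
#' rule is a replaceable policy; the raw coefficients are always retained.
#'
#' @param table A [correlation_table()].
#' @param dag A `bn_dag` covering the table's attributes.
#' @return The table with its `sc` matrix filled in.
#' @export
annotate_spurious <- function(table, dag) {
  stopifnot(inherits(table, "correlation_table"))
  attrs <- rownames(table$r)
  if (!all(attrs %in% dag$nodes)) {
    stop("DAG nodes must cover the correlation table attributes",
         call. = FALSE)
  }
  g <- as_igraph(dag)
  d <- igraph::distances(g, v = attrs, to = attrs, mode = "out")
  connected <- is.finite(d) | is.finite(t(d))
  table$sc <- !connected
  diag(table$sc) <- FALSE
  table
}

#' @export
print.correlation_table <- function(x, digits = 2, ...) {
  m <- format_correlation(x, digits)
  print(as.data.frame(m), right = TRUE)
  invisible(x)
}

format_correlation <- function(x, digits = 2) {
  m <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  up <- upper.tri(m, diag = TRUE)
  m[up] <- formatC(x$r[up], digits = digits, format = "g")
  m[up & x$sc] <- "SC"
  diag(m) <- "1"
  m
}

#' Write the correlation table as CSV
#'
#' Numeric cells carry the coefficient; flagged pairs carry the literal
#' token `SC`, mirroring the study's table layout (upper triangle).
#'
#' @param table A [correlation_table()].
#' @param path Output path.
#' @param digits Significant digits for coefficients.
#' @export
write_correlation_csv <- function(table, path, digits = 4) {
  utils::write.csv(format_correlation(table, digits), path)
  invisible(path)
}
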