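# Random-network builders and independent enumeration oracles. The oracles
# deliberately avoid the package's inference code path: probabilities are
# accumulated by explicit looping over complete assignments with direct CPT
# lookups.

rand_dag <- function(n, edge_prob = 0.4) {
  nodes <- paste0("V", seq_len(n))
  ord <- sample(nodes)
  edges <- NULL
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (runif(1) < edge_prob) edges <- rbind(edges, c(ord[i], ord[j]))
      }
    }
  }
  validate_dag(nodes, edges)
}

rand_bn <- function(n, edge_prob = 0.4) {
  dag <- rand_dag(n, edge_prob)
  cpts <- lapply(dag$nodes, function(v) {
    pa <- dag_parents(dag, v)
    make_cpt(v, pa, p1 = runif(2^length(pa), min = 0.05, max = 0.95))
  })
  names(cpts) <- dag$nodes
  bayesnet(dag, cpts, check = FALSE)
}

# direct CPT lookup for one full assignment (named character vector)
oracle_joint_one <- function(bn, a) {
  p <- 1
  for (v in bn$dag$nodes) {
    cpt <- bn$cpts[[v]]
    vars <- names(dimnames(cpt))
    idx <- integer(length(vars))
    for (i in seq_along(vars)) {
      idx[i] <- match(a[[vars[i]]], dimnames(cpt)[[i]])
    }
    p <- p * cpt[matrix(idx, nrow = 1)]
  }
  unname(p)
}

oracle_grid <- function(bn, free) {
  expand.grid(bn$states[free], stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

# exhaustive-enumeration conditional distribution of `target`
oracle_query <- function(bn, target, evidence = list()) {
  free <- setdiff(bn$dag$nodes, names(evidence))
  grid <- oracle_grid(bn, free)
  p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- c(as.list(grid[i, , drop = FALSE]), lapply(evidence, as.character))
    p[i] <- oracle_joint_one(bn, a)
  }
  out <- vapply(bn$states[[target]],
                function(s) sum(p[grid[[target]] == s]), numeric(1))
  out / sum(out)
}

# exhaustive-enumeration MAP completion
oracle_map <- function(bn, evidence = list()) {
  free <- setdiff(bn$dag$nodes, names(evidence))
  grid <- oracle_grid(bn, free)
  p <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- c(as.list(grid[i, , drop = FALSE]), lapply(evidence, as.character))
    p[i] <- oracle_joint_one(bn, a)
  }
  best <- c(as.list(grid[which.max(p), , drop = FALSE]),
            lapply(evidence, as.character))
  list(assignment = lapply(best, as.character)[bn$dag$nodes],
       probability = max(p))
}

# truncated-product interventional probability: set the treatment factor to
# a point mass and enumerate
oracle_do <- function(bn, outcome, treatment) {
  free <- setdiff(bn$dag$nodes, treatment$var)
  grid <- oracle_grid(bn, free)
  tot <- 0
  for (i in seq_len(nrow(grid))) {
    a <- c(as.list(grid[i, , drop = FALSE]),
           stats::setNames(list(treatment$state), treatment$var))
    if (a[[outcome$var]] != outcome$state) next
    p <- 1
    for (v in free) {   # skip the treatment's own CPT: truncated product
      cpt <- bn$cpts[[v]]
      vars <- names(dimnames(cpt))
      idx <- vapply(seq_along(vars),
                    function(k) match(a[[vars[k]]], dimnames(cpt)[[k]]),
                    integer(1))
      p <- p * cpt[matrix(idx, nrow = 1)]
    }
    tot <- tot + p
  }
  unname(tot)
}

# hand-coded networks used across tests
fourvar_bn <- function() {
  dag <- validate_dag(c("X", "Z", "Y", "W"),
                      rbind(c("X", "Y"), c("Y", "W"), c("Z", "W")))
  bayesnet(dag, list(
    X = make_cpt("X", p1 = 0.6),
    Z = make_cpt("Z", p1 = 0.3),
    Y = make_cpt("Y", "X", p1 = c(0.2, 0.9)),
    W = make_cpt("W", c("Y", "Z"), p1 = c(0.1, 0.7, 0.4, 0.8))))
}

confounder_bn <- function() {
  dag <- validate_dag(c("Z", "X", "Y"),
                      rbind(c("Z", "X"), c("Z", "Y"), c("X", "Y")))
  bayesnet(dag, list(
    Z = make_cpt("Z", p1 = 0.5),
    X = make_cpt("X", "Z", p1 = c(0.2, 0.8)),
    Y = make_cpt("Y", c("X", "Z"), p1 = c(0.1, 0.6, 0.5, 0.9))))
}

# study-shaped raw records: exact sex counts forced onto a synthetic sample
study_shaped_records <- function(n_total = 343, n_male = 49, seed = 11L) {
  cfg <- default_config(n_records = n_total, male_fraction = 0,
                        missing_rate = 0, seed = seed)
  rec <- sample_records(cfg)
  rec$sex <- rep("female", n_total)
  rec$sex[seq_len(n_male)] <- "male"
  rec
}

write_records_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
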