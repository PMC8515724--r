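test_that("DAG validation accepts acyclic graphs and reports cycles", {
  dag <- validate_dag(c("X", "Z", "Y", "W"),
                      rbind(c("X", "Y"), c("Y", "W"), c("Z", "W")))
  expect_s3_class(dag, "bn_dag")
  ord <- dag$order
  expect_lt(match("X", ord), match("Y", ord))
  expect_lt(match("Y", ord), match("W", ord))
  expect_lt(match("Z", ord), match("W", ord))

  expect_s3_class(validate_dag(c("A", "B")), "bn_dag")

  expect_error(validate_dag(c("A", "B"), rbind(c("A", "B"), c("B", "A"))),
               "cycle.*A.*B")
  expect_error(validate_dag("A", rbind(c("A", "Q"))), "endpoint")
})

test_that("CPT fitting matches hand counts and flags empty configurations", {
  dag1 <- validate_dag("X")
  bn1 <- fit_cpts(dag1, data.frame(X = rep(1, 5)))
  expect_equal(unname(bn1$cpts$X["1"]), 1)

  dag2 <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  d <- data.frame(A = c(0, 0, 1, 1), B = c(0, 1, 1, 1))
  bn2 <- fit_cpts(dag2, d)
  expect_equal(unname(bn2$cpts$B["1", "0"]), 0.5)
  expect_equal(unname(bn2$cpts$B["1", "1"]), 1.0)

  # Laplace smoothing: (count + a) / (n + 2a)
  bn3 <- fit_cpts(dag2, d, pseudocount = 1)
  expect_equal(unname(bn3$cpts$B["1", "1"]), 3 / 4)

  d_sparse <- data.frame(A = c(0, 0), B = c(0, 1))
  expect_error(fit_cpts(dag2, d_sparse), "parent configuration.*A.*1")
  expect_silent(fit_cpts(dag2, d_sparse, pseudocount = 1))
})

test_that("joint factorization reproduces the hand-computed product", {
  bn <- fourvar_bn()
  expect_equal(joint_probability(bn, list(X = "1", Z = "0", Y = "1", W = "1")),
               0.6 * 0.7 * 0.9 * 0.7)
  expect_error(joint_probability(bn, list(X = "1")), "missing")

  # uniform independent nodes: every assignment has probability 2^-n
  dag <- validate_dag(c("A", "B", "C"))
  bnu <- bayesnet(dag, list(A = make_cpt("A", p1 = .5),
                            B = make_cpt("B", p1 = .5),
                            C = make_cpt("C", p1 = .5)))
  expect_equal(joint_probability(bnu, list(A = "0", B = "1", C = "0")), 1 / 8)
})

test_that("the joint sums to one over all full assignments", {
  set.seed(301)
  for (rep in 1:10) {
    bn <- rand_bn(sample(3:8, 1))
    grid <- oracle_grid(bn, bn$dag$nodes)
    tot <- sum(vapply(seq_len(nrow(grid)), function(i) {
      joint_probability(bn, as.list(grid[i, , drop = FALSE]))
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("conditional queries invert a chain by Bayes rule", {
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- bayesnet(dag, list(A = make_cpt("A", p1 = .5),
                           B = make_cpt("B", "A", p1 = c(.1, .9))))
  expect_equal(unname(query(bn, "A", list(B = "1"))["1"]), 0.9)
  # conditioning a target on itself gives a point mass
  expect_equal(unname(query(bn, "B", list(B = "0"))), c(1, 0))
})

test_that("impossible evidence is rejected as such", {
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- bayesnet(dag, list(A = make_cpt("A", p1 = 1),
                           B = make_cpt("B", "A", p1 = c(0, 1))))
  expect_error(query(bn, "A", list(B = "0")), "impossible evidence")
  expect_error(map_assignment(bn, list(B = "0")), "impossible evidence")
  expect_error(query(bn, "A", list(B = "7")), "unknown state")
})

test_that("variable elimination matches the enumeration oracle", {
  set.seed(302)
  for (rep in 1:30) {
    bn <- rand_bn(sample(3:8, 1))
    nodes <- bn$dag$nodes
    target <- sample(nodes, 1)
    n_ev <- sample(0:min(2, length(nodes) - 1), 1)
    ev_vars <- sample(setdiff(nodes, target), n_ev)
    ev <- stats::setNames(as.list(sample(c("0", "1"), n_ev,
                                         replace = TRUE)), ev_vars)
    expect_equal(unname(query(bn, target, ev)),
                 unname(oracle_query(bn, target, ev)),
                 tolerance = 1e-9)
  }
})

test_that("max-product MAP equals the brute-force argmax", {
  set.seed(303)
  for (rep in 1:30) {
    bn <- rand_bn(sample(3:8, 1))
    nodes <- bn$dag$nodes
    n_ev <- sample(0:2, 1)
    ev_vars <- sample(nodes, n_ev)
    ev <- stats::setNames(as.list(sample(c("0", "1"), n_ev,
                                         replace = TRUE)), ev_vars)
    got <- map_assignment(bn, ev)
    want <- oracle_map(bn, ev)
    expect_identical(got$assignment, want$assignment)
    expect_equal(got$probability, want$probability, tolerance = 1e-12)
  }

  # no evidence, independent nodes: per-node argmax of the marginals
  dag <- validate_dag(c("A", "B"))
  bn <- bayesnet(dag, list(A = make_cpt("A", p1 = .8),
                           B = make_cpt("B", p1 = .1)))
  expect_identical(map_assignment(bn)$assignment, list(A = "1", B = "0"))
})

test_that("MAP ties resolve to the lexicographically smallest maximizer", {
  dag <- validate_dag(c("A", "B"))
  bn <- bayesnet(dag, list(A = make_cpt("A", p1 = .5),
                           B = make_cpt("B", p1 = .2)))
  expect_warning(m <- map_assignment(bn), "not unique")
  expect_identical(m$assignment, list(A = "0", B = "0"))
})

test_that("the Markov condition yields A independent of C given B in a chain", {
  set.seed(304)
  for (rep in 1:5) {
    dag <- validate_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
    bn <- bayesnet(dag, list(
      A = make_cpt("A", p1 = runif(1, .1, .9)),
      B = make_cpt("B", "A", p1 = runif(2, .1, .9)),
      C = make_cpt("C", "B", p1 = runif(2, .1, .9))))
    for (b in c("0", "1")) {
      p_given_ab <- query(bn, "C", list(A = "1", B = b))
      p_given_b <- query(bn, "C", list(B = b))
      expect_equal(unname(p_given_ab), unname(p_given_b), tolerance = 1e-9)
    }
  }
})

test_that("large-sample CPT fitting converges to the generating network", {
  set.seed(305)
  # a two-parent network keeps every configuration well populated at n=50000
  dag <- validate_dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  truth <- bayesnet(dag, list(
    A = make_cpt("A", p1 = .6), B = make_cpt("B", p1 = .35),
    C = make_cpt("C", c("A", "B"), p1 = c(.15, .5, .7, .9))))
  n <- 50000
  a <- as.integer(runif(n) < .6)
  b <- as.integer(runif(n) < .35)
  pc <- c(.15, .5, .7, .9)[1 + a + 2 * b]
  d <- data.frame(A = a, B = b, C = as.integer(runif(n) < pc))
  fit <- fit_cpts(dag, d)
  for (v in dag$nodes) {
    expect_lt(max(abs(fit$cpts[[v]] - truth$cpts[[v]])), 0.02)
  }
})

test_that("JSON serialization round-trips losslessly", {
  set.seed(306)
  for (bn in list(fourvar_bn(), confounder_bn(), rand_bn(6))) {
    f <- withr::local_tempfile(fileext = ".json")
    write_bn_json(bn, f)
    back <- read_bn_json(f)
    expect_identical(back$dag$nodes, bn$dag$nodes)
    expect_equal(back$cpts, bn$cpts, tolerance = 1e-15)
  }
})

test_that("edge lists round-trip through the plain-text format", {
  dag <- study_dag()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(dag, f)
  back <- read_edge_list(f, nodes = dag$nodes)
  expect_setequal(paste(back$edges[, 1], back$edges[, 2]),
                  paste(dag$edges[, 1], dag$edges[, 2]))
})
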